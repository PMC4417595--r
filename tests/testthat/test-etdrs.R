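# A 61 x 61 grid at 100 um/pixel spans 6 mm: the full ETDRS disk fits.
std_grid <- function(eye = "OD")
  sector_grid(c(61L, 61L), center = c(30, 30),
              lateral_spacing_um = c(100, 100), eye_side = eye)

test_that("sector_grid places rings, quadrants, and mirroring correctly", {
  g <- std_grid()
  expect_equal(g$labels[31, 31], 1L)          # center pixel
  expect_equal(g$labels[41, 31], 3L)          # 1 mm nasal (+x, OD): parafoveal
  expect_equal(g$labels[51, 31], 7L)          # 2 mm nasal: perifoveal
  gos <- std_grid("OS")
  expect_equal(gos$labels[41, 31], 5L)        # same pixels, OS -> temporal
  expect_equal(gos$labels[51, 31], 9L)
  expect_equal(g$labels[31, 11], 6L)          # 2 mm superior (-z), perifoveal
  expect_setequal(unique(as.vector(g$labels)), 0:9)

  # every in-disk pixel has exactly one label; outside is 0
  dx <- (row(g$labels) - 31) * 100; dz <- (col(g$labels) - 31) * 100
  rr <- sqrt(dx^2 + dz^2)
  expect_true(all(g$labels[rr < 3000] > 0))
  expect_true(all(g$labels[rr >= 3000] == 0))
  expect_error(sector_grid(c(10L, 10L), c(50, 0), c(100, 100), "OD"),
               "outside")
  expect_warning(sector_grid(c(11L, 11L), c(5, 5), c(100, 100), "OD"),
                 "exceeds")
})

test_that("mirroring is an involution and swaps 3<->5, 7<->9", {
  g <- std_grid("OD")
  gos <- std_grid("OS")
  swap <- c(1L, 2L, 5L, 4L, 3L, 6L, 9L, 8L, 7L)
  relab <- gos$labels
  relab[gos$labels > 0] <- swap[gos$labels[gos$labels > 0]]
  expect_identical(relab, g$labels)
  # double mirroring: applying the swap twice is the identity
  relab2 <- relab
  relab2[relab > 0] <- swap[relab[relab > 0]]
  expect_identical(relab2, gos$labels)
})

test_that("sector_stats: constant map, hand arithmetic, exclusions", {
  g <- std_grid()
  st <- sector_stats(matrix(100, 61, 61), g)
  expect_equal(st$mean_um, rep(100, 9))
  expect_equal(st$sd_um, rep(0, 9))
  expect_true(all(st$n_pixels > 0))

  m <- matrix(100, 61, 61)
  sel <- which(g$labels == 2)
  m[sel] <- 100
  m[sel[1]] <- 10; m[sel[2]] <- 20
  m[sel[-(1:2)]] <- NA                      # flagged pixels excluded
  st2 <- sector_stats(m, g)
  expect_equal(st2$mean_um[2], 15)
  expect_equal(st2$sd_um[2], sd(c(10, 20)))
  expect_equal(st2$n_pixels[2], 2L)
  expect_error(sector_stats(matrix(0, 3, 3), g), "identical|dim")
})

test_that("t-test matches brute force and its conventions", {
  r0 <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- unpaired_t_test(a, b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  tman <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  pman <- 2 * pt(-abs(tman), 4)
  expect_equal(r$statistic, tman, tolerance = 1e-12)
  expect_equal(r$p_value, pman, tolerance = 1e-12)

  rswap <- unpaired_t_test(b, a)
  expect_equal(rswap$statistic, -r$statistic)
  expect_equal(rswap$p_value, r$p_value)

  expect_equal(unpaired_t_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(unpaired_t_test(c(2, 2), c(1, 1))$p_value, 0)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("anova_f equals t squared on two groups and handles degeneracy", {
  set.seed(31)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  tt <- unpaired_t_test(a, b)
  ff <- anova_f(list(a, b))
  expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(ff$p_value, tt$p_value, tolerance = 1e-9)

  g3 <- anova_f(list(rnorm(5), rnorm(5), rnorm(5)))
  expect_true(is.finite(g3$statistic) && g3$p_value > 0 && g3$p_value < 1)
  dg <- anova_f(list(c(1, 1), c(2, 2)))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)
  expect_error(anova_f(list(rnorm(3))), "2")
})

test_that("slope_test matches normal equations and conventions", {
  x <- 1:10
  expect_equal(slope_test(x, rep(4, 10))$effect, 0)
  expect_equal(slope_test(x, rep(4, 10))$p_value, 1)
  # base R's summary.lm warns on an exact fit; the convention is still tested
  r2 <- suppressWarnings(slope_test(x, 2 * x))
  expect_equal(r2$effect, 2)
  expect_lt(r2$p_value, 1e-10)

  set.seed(17)
  y <- 1.5 * x + rnorm(10)
  r <- slope_test(x, y)
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - mean(y) - bx * (x - mean(x))
  se <- sqrt(sum(res^2) / 8 / sum((x - mean(x))^2))
  expect_equal(r$effect, bx, tolerance = 1e-12)
  expect_equal(r$statistic, bx / se, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(-abs(bx / se), 8), tolerance = 1e-12)
  expect_error(slope_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("cohort_report runs per layer/sector and skips single-sex tests", {
  set.seed(23)
  g <- std_grid()
  mk_table <- function(total) {
    d <- array(0, c(61, 61, 12))
    for (s in 1:12) d[, , s] <- (s - 1) * total / 11
    sector_table(compute_thickness_maps(surface_set(d), 1), g)
  }
  ages <- runif(12, 20, 80)
  sexes <- rep(c("M", "F"), 6)
  tabs <- lapply(300 + 2 * (sexes == "M") - 0.1 * ages + rnorm(12), mk_table)
  rep1 <- cohort_report(tabs, ages, sexes)
  expect_true(all(c("sex_p", "age_p") %in% names(rep1)))
  expect_equal(nrow(rep1), 12 * 9)
  expect_message(cohort_report(tabs, ages, rep("F", 12)), "single-sex")
  bf <- cohort_report(tabs, ages, sexes, bonferroni = TRUE)
  expect_true(all(bf$age_p >= rep1$age_p - 1e-15))
  expect_error(cohort_report(tabs[1:2], ages[1:2], sexes[1:2]), "3")
})
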