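# ETDRS 9-sector macular grid, per-sector summaries, and cohort statistics
# (sex comparison by unpaired t-test, age association by the slope test of a
# linear regression, multi-sector comparison by one-way ANOVA / F test).

#' Build the ETDRS 9-sector grid
#'
#' Three concentric circles (default diameters 1 / 3 / 6 mm) centered on the
#' fovea. Sector 1 is the central circle; the parafoveal ring is split into
#' superior (2), nasal (3), inferior (4) and temporal (5); the perifoveal
#' ring into superior (6), nasal (7), inferior (8) and temporal (9). Ring
#' boundaries are half-open (inner-inclusive). Quadrants are split by the
#' +/-45 degree diagonals through the center; pixels exactly on a diagonal go
#' to the superior/inferior sectors. For OD eyes nasal is the +x direction,
#' for OS eyes -x (so labels 3<->5 and 7<->9 are mirrored between eyes);
#' superior is -z.
#'
#' @param shape Integer `(nx, nz)` grid dimensions.
#' @param center `(x, z)` 0-based foveal center (real-valued allowed).
#' @param lateral_spacing_um `(x, z)` micrometers per pixel.
#' @param eye_side `"OD"` or `"OS"`.
#' @param diameters_mm Central/inner/outer circle diameters, default
#'   `c(1, 3, 6)` mm.
#' @return Object of class `sector_map`: integer `labels` matrix (0 outside
#'   the grid), plus the construction parameters.
#' @export
sector_grid <- function(shape, center, lateral_spacing_um, eye_side,
                        diameters_mm = c(1, 3, 6)) {
  stopifnot(length(shape) == 2L, length(center) == 2L,
            all(lateral_spacing_um > 0), length(diameters_mm) == 3L,
            all(diff(diameters_mm) > 0))
  eye_side <- match.arg(eye_side, c("OD", "OS"))
  if (center[1] < 0 || center[1] > shape[1] - 1 ||
      center[2] < 0 || center[2] > shape[2] - 1)
    stop("center outside the grid")
  radii_um <- diameters_mm / 2 * 1000
  dx <- ((seq_len(shape[1]) - 1) - center[1]) * lateral_spacing_um[1]
  dz <- ((seq_len(shape[2]) - 1) - center[2]) * lateral_spacing_um[2]
  DX <- matrix(dx, shape[1], shape[2])
  DZ <- matrix(dz, shape[1], shape[2], byrow = TRUE)
  rr <- sqrt(DX^2 + DZ^2)
  ring <- matrix(0L, shape[1], shape[2])
  ring[rr < radii_um[1]] <- 1L
  ring[rr >= radii_um[1] & rr < radii_um[2]] <- 2L
  ring[rr >= radii_um[2] & rr < radii_um[3]] <- 3L
  # quadrants: superior = -z, inferior = +z, nasal = +x (OD) / -x (OS)
  nasal_x <- if (eye_side == "OD") DX else -DX
  quad <- matrix(0L, shape[1], shape[2])
  quad[DZ < 0 & abs(DZ) >= abs(DX)] <- 1L   # superior
  quad[nasal_x > 0 & abs(DX) > abs(DZ)] <- 2L   # nasal
  quad[DZ > 0 & abs(DZ) >= abs(DX)] <- 3L   # inferior
  quad[nasal_x < 0 & abs(DX) > abs(DZ)] <- 4L   # temporal
  labels <- matrix(0L, shape[1], shape[2])
  labels[ring == 1L] <- 1L
  sel2 <- ring == 2L
  labels[sel2] <- 1L + quad[sel2]
  sel3 <- ring == 3L
  labels[sel3] <- 5L + quad[sel3]
  if (max(rr[1, 1], rr[shape[1], 1], rr[1, shape[2]],
          rr[shape[1], shape[2]]) < radii_um[3])
    warning("outer ETDRS circle exceeds the grid extent; ",
            "peripheral sectors are partial")
  structure(list(labels = labels, center = center,
                 diameters_mm = diameters_mm, eye_side = eye_side,
                 lateral_spacing_um = lateral_spacing_um),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("ETDRS sector map (%s): %d x %d grid, circles %s mm,\n",
              x$eye_side, nrow(x$labels), ncol(x$labels),
              paste(x$diameters_mm, collapse = "/")))
  cat(sprintf("  center (%.1f, %.1f); pixels per sector: %s\n",
              x$center[1], x$center[2],
              paste(tabulate(x$labels[x$labels > 0], 9), collapse = ", ")))
  invisible(x)
}

#' Per-sector mean and SD of a thickness map
#'
#' Sample SD (n-1 denominator); `NA`/flagged pixels are excluded from both
#' the statistics and the pixel counts. Empty sectors are reported as absent
#' (`NA` mean/SD, `n_pixels = 0`), never as zero.
#'
#' @param map Numeric (x, z) thickness matrix (um); `NA` marks excluded
#'   pixels.
#' @param sectors A [sector_grid()] result on the same grid.
#' @return Data frame with columns `sector` (1..9), `mean_um`, `sd_um`,
#'   `n_pixels`.
#' @export
sector_stats <- function(map, sectors) {
  stopifnot(inherits(sectors, "sector_map"),
            identical(dim(map), dim(sectors$labels)))
  out <- data.frame(sector = 1:9, mean_um = NA_real_, sd_um = NA_real_,
                    n_pixels = 0L)
  for (s in 1:9) {
    v <- map[sectors$labels == s]
    v <- v[is.finite(v)]
    out$n_pixels[s] <- length(v)
    if (length(v)) {
      out$mean_um[s] <- mean(v)
      out$sd_um[s] <- if (length(v) > 1L) sd(v) else 0
    }
  }
  out
}

#' Per-sector summary of all layers plus total retina
#'
#' @param maps A `thickness_maps` object.
#' @param sectors A [sector_grid()] result.
#' @return Long data frame: `layer` (1..11 or "total"), `sector`, `mean_um`,
#'   `sd_um`, `n_pixels`.
#' @export
sector_table <- function(maps, sectors) {
  stopifnot(inherits(maps, "thickness_maps"))
  rows <- lapply(1:11, function(l) {
    cbind(layer = as.character(l), sector_stats(maps$per_layer[, , l], sectors))
  })
  rows <- c(rows, list(cbind(layer = "total",
                             sector_stats(maps$total, sectors))))
  do.call(rbind, rows)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return List of class `stat_result`: `statistic`, `p_value`, `df`,
#'   `effect` (mean of `a` minus mean of `b`).
#' @export
unpaired_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values")
  eff <- mean(a) - mean(b)
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled <= 0) {
    # degenerate: no within-group variance at all
    res <- list(statistic = if (eff == 0) 0 else sign(eff) * Inf,
                p_value = if (eff == 0) 1 else 0,
                df = length(a) + length(b) - 2L, effect = eff,
                degenerate = TRUE)
    class(res) <- "stat_result"
    return(res)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 effect = eff, degenerate = FALSE),
            class = "stat_result")
}

#' One-way ANOVA with F test
#'
#' Tests the null that all group means are equal: `F` is the between-group
#' mean square over the within-group mean square.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2 values).
#' @return A `stat_result` with `statistic` (F), `p_value`, `df`
#'   (numerator, denominator), `effect` (between-group variance of means).
#' @export
anova_f <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  if (!is.finite(ow$statistic)) {
    means <- vapply(groups, mean, numeric(1))
    degen <- list(statistic = Inf,
                  p_value = if (var(means) > 0) 0 else 1,
                  df = unname(ow$parameter), effect = var(means),
                  degenerate = TRUE)
    class(degen) <- "stat_result"
    return(degen)
  }
  structure(list(statistic = unname(ow$statistic), p_value = ow$p.value,
                 df = unname(ow$parameter),
                 effect = var(vapply(groups, mean, numeric(1))),
                 degenerate = FALSE),
            class = "stat_result")
}

#' Hypothesis test for the slope of a linear regression
#'
#' Least-squares fit of `y ~ x`; two-sided t test of the slope against zero.
#' A perfectly constant response returns slope 0 with p = 1.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be constant.
#' @return A `stat_result` with `statistic` (t), `p_value`, `df`, `effect`
#'   (the slope), and `se`.
#' @export
slope_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (var(x) == 0) stop("x is constant; slope is undefined")
  if (var(y) == 0)
    return(structure(list(statistic = 0, p_value = 1,
                          df = length(x) - 2L, effect = 0, se = 0),
                     class = "stat_result"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  tstat <- sm["x", "t value"]
  p <- sm["x", "Pr(>|t|)"]
  if (!is.finite(se) || se == 0) {
    # zero residual variance: p degenerates to 1 (flat) or ~0 (exact trend)
    p <- if (abs(slope) <= .Machine$double.eps^0.5) 1 else 0
    tstat <- if (p == 1) 0 else sign(slope) * Inf
  }
  structure(list(statistic = unname(tstat), p_value = unname(p),
                 df = fit$df.residual, effect = unname(slope),
                 se = unname(se)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, df = %s, p = %.4g, effect = %.4g\n",
              x$statistic, paste(round(x$df, 2), collapse = "/"),
              x$p_value, x$effect))
  invisible(x)
}

#' Cohort statistics: sex comparison and age association per layer and sector
#'
#' For every (layer, sector) cell -- the 11 layers plus the total retina --
#' compares sector-mean thickness between sexes with an unpaired t-test and
#' tests its association with age via the regression slope test. No
#' multiplicity correction is applied by default; set `bonferroni = TRUE` to
#' adjust p-values across cells.
#'
#' @param sector_tables List of per-subject [sector_table()] data frames.
#' @param ages Numeric vector of subject ages (years).
#' @param sexes Character vector, `"M"`/`"F"`.
#' @param bonferroni Apply a Bonferroni correction across cells.
#' @return Data frame: `layer`, `sector`, `mean_um`, `sex_diff_um` (M - F),
#'   `sex_t`, `sex_p`, `age_slope_um_per_year`, `age_t`, `age_p`.
#' @export
cohort_report <- function(sector_tables, ages, sexes, bonferroni = FALSE) {
  n <- length(sector_tables)
  if (n < 3L) stop("need at least 3 subjects")
  stopifnot(length(ages) == n, length(sexes) == n)
  both_sexes <- length(unique(sexes)) > 1L
  if (!both_sexes)
    message("single-sex cohort: sex comparisons skipped")
  layers <- unique(sector_tables[[1]]$layer)
  out <- list()
  for (lay in layers) for (sec in 1:9) {
    vals <- vapply(sector_tables, function(tb)
      tb$mean_um[tb$layer == lay & tb$sector == sec], numeric(1))
    if (all(!is.finite(vals))) next
    row <- data.frame(layer = lay, sector = sec, mean_um = mean(vals),
                      sex_diff_um = NA_real_, sex_t = NA_real_,
                      sex_p = NA_real_, age_slope_um_per_year = NA_real_,
                      age_t = NA_real_, age_p = NA_real_)
    if (both_sexes && sum(sexes == "M") >= 2L && sum(sexes == "F") >= 2L) {
      st <- unpaired_t_test(vals[sexes == "M"], vals[sexes == "F"])
      row$sex_diff_um <- st$effect
      row$sex_t <- st$statistic
      row$sex_p <- st$p_value
    }
    sl <- slope_test(ages, vals)
    row$age_slope_um_per_year <- sl$effect
    row$age_t <- sl$statistic
    row$age_p <- sl$p_value
    out[[length(out) + 1L]] <- row
  }
  rep <- do.call(rbind, out)
  if (bonferroni) {
    rep$sex_p <- pmin(rep$sex_p * nrow(rep), 1)
    rep$age_p <- pmin(rep$age_p * nrow(rep), 1)
  }
  rep
}
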