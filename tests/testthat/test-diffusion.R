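test_that("build_nodes pools blocks with the stated count and features", {
  a <- array(0.5, c(4, 4, 4)); a[1] <- 0.4   # avoid constant-volume rejection
  v <- oct_volume(a, c(1, 1, 1))
  ns <- build_nodes(v, c(2L, 2L, 2L))
  expect_equal(ns$n, 8L)
  expect_equal(ns$features[2], 0.5)

  b <- array(rep(c(0, 1), each = 4), c(2, 2, 2))
  vb <- oct_volume(b, c(1, 1, 1))
  expect_error(build_nodes(vb, c(2L, 2L, 2L)), "fewer than 2 nodes")
})

test_that("build_nodes mean vs lower-median block summaries", {
  b <- array(c(0, 0, 0, 0, 1, 1, 1, 1, rep(0.5, 8)), c(4, 2, 2))
  vb <- oct_volume(b, c(1, 1, 1))
  nb <- build_nodes(vb, c(4L, 2L, 1L))
  expect_equal(nb$features[1], 0.5)            # mean of {0 x4, 1 x4}
  nm <- build_nodes(vb, c(4L, 2L, 1L), feature_stat = "median")
  expect_equal(nm$features[1], 0)              # lower median: observed value
  # every voxel belongs to exactly one node
  expect_true(all(!is.na(nb$node_of_voxel)))
  expect_error(build_nodes(vb, c(8L, 2L, 1L)), "larger")
  expect_error(build_nodes(vb, c(4L, 2L, 1L),
                           mask = array(FALSE, c(4, 2, 2))), "empty mask")
})

test_that("estimate_scale applies the 0.15-range rule", {
  expect_equal(estimate_scale(matrix(c(0, 0, 10, 0), 2)), 1.5)
  expect_equal(estimate_scale(matrix(c(0, 2, 6, 0), 2)), 0.6)
  expect_error(estimate_scale(matrix(c(0, 3, 3, 0), 2)), "degenerate")
})

test_that("kernel contract: symmetry, support, diagonal, worked value", {
  cfg <- diffusion_config(sigma_feature = 0.1, sigma_geo = 1, radius = 2,
                          position_units = "voxel")
  k <- compute_kernel(two_node_set(), cfg)
  expect_equal(k$k[1, 2], exp(-1))
  expect_equal(k$k[1, 1], 1)
  expect_equal(k$k[2, 2], 1)

  set.seed(11)
  n <- 60
  ns <- structure(list(features = runif(n),
                       positions = cbind(runif(n, 0, 6), runif(n, 0, 6),
                                         runif(n, 0, 6)),
                       position_units = "voxel", n = n),
                  class = "node_set")
  cfg2 <- diffusion_config(sigma_feature = 0.2, sigma_geo = 2, radius = 3,
                           position_units = "voxel")
  K <- as.matrix(compute_kernel(ns, cfg2)$k)
  expect_identical(K, t(K))
  expect_true(all(K >= 0))
  D <- as.matrix(dist(ns$positions))
  expect_true(all(K[D >= 3] == 0))
  expect_equal(diag(K), rep(1, n))
})

test_that("isolated nodes are rejected with advice", {
  ns <- structure(list(features = c(0.1, 0.9),
                       positions = rbind(c(0, 0, 0), c(50, 0, 0)),
                       position_units = "voxel", n = 2L),
                  class = "node_set")
  cfg <- diffusion_config(sigma_feature = 0.1, sigma_geo = 1, radius = 2,
                          position_units = "voxel")
  expect_error(compute_kernel(ns, cfg), "isolated")
})

test_that("markov_normalize reproduces the worked examples", {
  tm <- markov_normalize(matrix(1, 2, 2))
  expect_equal(as.matrix(tm$P), matrix(0.5, 2, 2), ignore_attr = TRUE)

  K <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3)
  tm3 <- markov_normalize(K)
  expect_equal(as.matrix(tm3$P),
               rbind(c(2, 1, 0) / 3, c(1, 2, 1) / 4, c(0, 1, 2) / 3),
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_error(markov_normalize(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(markov_normalize(matrix(c(1, -0.1, -0.1, 1), 2)),
               "nonnegative")
  Z <- diag(c(1, 0)); Z[] <- 0
  expect_error(markov_normalize(Z), "zero row sum")
})

test_that("rows of P sum to one on random kernels", {
  set.seed(42)
  worst <- 0
  for (rep in 1:25) {
    tm <- markov_normalize(random_kernel(sample(5:120, 1)))
    worst <- max(worst, max(abs(Matrix::rowSums(tm$P) - 1)))
  }
  expect_lt(worst, 1e-12)
})

test_that("two-state chain eigenvalue and spectral bound", {
  for (ab in list(c(0.5, 0.5), c(0.3, 0.6), c(0.05, 0.9))) {
    a <- ab[1]; b <- ab[2]
    K <- matrix(c((1 - a) / a, 1, 1, (1 - b) / b), 2)
    emb <- diffusion_embed(markov_normalize(K), omega = 1L, tau = 1L)
    expect_equal(emb$values[1], 1 - a - b, tolerance = 1e-12)
  }
  set.seed(5)
  emb2 <- diffusion_embed(markov_normalize(random_kernel(80)),
                          omega = 10L, tau = 1L)
  expect_true(all(abs(emb2$values) <= 1 + 1e-9))
  expect_true(all(is.finite(emb2$coordinates)))
  expect_error(diffusion_embed(markov_normalize(random_kernel(5)),
                               omega = 5L), "omega")
})

test_that("diffusion time monotonically shrinks coordinates", {
  set.seed(6)
  tm <- markov_normalize(random_kernel(50))
  e1 <- diffusion_embed(tm, omega = 6L, tau = 1L)
  e2 <- diffusion_embed(tm, omega = 6L, tau = 2L)
  n1 <- sqrt(rowSums(e1$coordinates^2))
  n2 <- sqrt(rowSums(e2$coordinates^2))
  expect_true(all(n2 <= n1 + 1e-12))
})

test_that("clustering in embedding space is seeded and separates clouds", {
  set.seed(9)
  km <- component_kernel(c(40, 35, 30))
  tm <- markov_normalize(km$k)
  emb <- diffusion_embed(tm, omega = 2L, tau = 1L)
  lab <- cluster_embedding(emb, 3L, seed = 4L)
  expect_true(same_partition(lab, km$membership))
  expect_identical(lab, cluster_embedding(emb, 3L, seed = 4L))
  expect_identical(cluster_embedding(emb, 1L, seed = 1L), rep(1L, 105))
  expect_error(cluster_embedding(emb, 1000L, seed = 1L), "exceeds")
  # label-permutation invariance of cluster quality across seeds
  wss <- function(l) sum(vapply(split(seq_along(l), l), function(ix) {
    X <- emb$coordinates[ix, , drop = FALSE]
    sum(scale(X, scale = FALSE)^2)
  }, numeric(1)))
  expect_equal(wss(lab), wss(cluster_embedding(emb, 3L, seed = 99L)),
               tolerance = 1e-9)
})
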