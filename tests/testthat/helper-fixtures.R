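# Shared fixtures for the test suite.

# Random symmetric nonnegative kernel with unit diagonal (a "valid kernel"
# in the sense of the Markov-normalization contract).
random_kernel <- function(n) {
  A <- matrix(runif(n * n), n, n)
  K <- (A + t(A)) / 2
  diag(K) <- 1
  K
}

# Block-diagonal kernel with `sizes` components; within-component affinities
# are random positive, across-component exactly zero.
component_kernel <- function(sizes) {
  n <- sum(sizes)
  K <- matrix(0, n, n)
  stop_at <- cumsum(sizes)
  start_at <- stop_at - sizes + 1L
  for (c in seq_along(sizes)) {
    idx <- start_at[c]:stop_at[c]
    A <- matrix(runif(length(idx)^2, 0.2, 1), length(idx))
    K[idx, idx] <- (A + t(A)) / 2
  }
  diag(K) <- 1
  list(k = K, membership = rep(seq_along(sizes), sizes))
}

# Hand-constructed two-node node_set realizing the worked kernel example:
# feature distance 0.1, geometric distance 1.
two_node_set <- function() {
  structure(list(features = c(0.2, 0.3),
                 positions = rbind(c(0, 0, 0), c(1, 0, 0)),
                 centroid_voxels = rbind(c(0, 0, 0), c(1, 0, 0)),
                 grid = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                 node_of_voxel = NULL, block_shape = c(1L, 1L, 1L),
                 position_units = "voxel", feature_stat = "mean", n = 2L),
            class = "node_set")
}

# Small fast phantom for segmentation tests (same anatomy as the default,
# fewer lateral samples).
small_phantom_config <- function(...) {
  phantom_config(shape = c(32L, 128L, 8L), ...)
}

# True/false equality of two clusterings up to label permutation.
same_partition <- function(a, b) {
  tb <- table(a, b)
  all(rowSums(tb > 0) == 1L) && all(colSums(tb > 0) == 1L)
}
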