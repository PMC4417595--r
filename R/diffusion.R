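# Coarse-grained diffusion-map machinery: voxel pooling into graph nodes,
# sparse product Gaussian kernel, Markov normalization, spectral embedding,
# and clustering in embedding space.

#' Diffusion-map configuration
#'
#' @param block_shape Integer length-3 vector: voxels pooled into one graph
#'   node along x, y (axial), z.
#' @param sigma_feature Gaussian scale for intensity distances, or `"auto"`
#'   to apply the 0.15-times-range rule ([estimate_scale()]) to a seeded
#'   subsample of node pairs.
#' @param sigma_geo Gaussian scale for geometric distances, or `"auto"`.
#' @param radius Neighborhood radius `r`: kernel entries are zero at geometric
#'   distance `>= r`. Interpreted in the units of the node positions (see
#'   `position_units`). A length-3 vector gives an anisotropic (ellipsoidal)
#'   neighborhood, `sum((dx, dy, dz) / r)^2 < 1` -- useful when the physical
#'   voxel pitch differs strongly between axes.
#' @param omega Embedding dimension (number of retained eigenpairs after the
#'   stationary one is dropped).
#' @param tau Diffusion time: embedding coordinates are `lambda_i^tau psi_i`.
#' @param n_clusters Number of k-means clusters in embedding space.
#' @param seed Integer seed controlling scale subsampling, eigensolver start
#'   and k-means restarts.
#' @param position_units `"block"` (default): kernel geometry uses voxel
#'   centroids divided by the block pitch, so inter-node spacing is isotropic
#'   and `radius` counts node steps; `"voxel"`: raw voxel-unit centroids.
#' @param feature_scale_factor Multiple of the feature-distance range used
#'   when `sigma_feature = "auto"`; 0.15 is the recommended general-purpose
#'   value, smaller values sharpen the discrimination between regions whose
#'   intensity difference is a small fraction of the overall range.
#' @param feature_stat Block intensity summary used by [build_nodes()]:
#'   `"mean"` or `"median"` (robust to blocks straddling sharp boundaries).
#' @return A list of class `diffusion_config`.
#' @export
diffusion_config <- function(block_shape = c(4L, 4L, 1L),
                             sigma_feature = "auto", sigma_geo = "auto",
                             radius = 3, omega = 3L, tau = 1L,
                             n_clusters = 3L, seed = 1L,
                             position_units = c("block", "voxel"),
                             feature_scale_factor = 0.15,
                             feature_stat = c("mean", "median")) {
  position_units <- match.arg(position_units)
  feature_stat <- match.arg(feature_stat)
  block_shape <- as.integer(block_shape)
  stopifnot(length(block_shape) == 3L, all(block_shape >= 1L),
            radius > 0, omega >= 1L, tau >= 1L, n_clusters >= 1L,
            feature_scale_factor > 0)
  structure(list(block_shape = block_shape, sigma_feature = sigma_feature,
                 sigma_geo = sigma_geo, radius = radius,
                 omega = as.integer(omega), tau = as.integer(tau),
                 n_clusters = as.integer(n_clusters), seed = as.integer(seed),
                 position_units = position_units,
                 feature_scale_factor = feature_scale_factor,
                 feature_stat = feature_stat),
            class = "diffusion_config")
}

#' Pool voxels into graph nodes
#'
#' Voxels are grouped into rectangular/cubic blocks; each block intersecting
#' the mask becomes one node whose feature is a summary intensity (mean or
#' median) of its in-mask voxels and whose position is their centroid.
#' The median is preferable when blocks may straddle sharp boundaries: a
#' straddling block then reports the majority side's intensity rather than
#' an intermediate mixture value, which would otherwise bridge (or, in the
#' extreme, disconnect from) both sides in the affinity graph.
#'
#' @param volume An [oct_volume].
#' @param block_shape Integer length-3 block size along x, y, z; blocks tile
#'   the array (edge blocks may be smaller).
#' @param mask Optional logical array congruent with the volume; only in-mask
#'   voxels are pooled.
#' @param position_units `"block"` or `"voxel"`, see [diffusion_config()].
#' @param feature_stat `"mean"` or `"median"` block intensity summary.
#' @return A list of class `node_set` with elements `features` (n-vector in
#'   `[0, 1]`), `positions` (n x 3 matrix in the requested units),
#'   `centroid_voxels` (n x 3 voxel-unit centroids, 0-based), `grid`
#'   (n x 3 integer block indices), `node_of_voxel` (integer array congruent
#'   with the volume, `NA` outside the mask), `block_shape`, `n`.
#' @export
build_nodes <- function(volume, block_shape, mask = NULL,
                        position_units = c("block", "voxel"),
                        feature_stat = c("mean", "median")) {
  stopifnot(inherits(volume, "oct_volume"))
  position_units <- match.arg(position_units)
  feature_stat <- match.arg(feature_stat)
  dims <- dim(volume$intensities)
  block_shape <- as.integer(block_shape)
  if (any(block_shape > dims))
    stop("block_shape larger than the volume")
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dims))
    idx <- which(mask)
    if (!length(idx)) stop("empty mask")
  } else {
    idx <- seq_len(prod(dims))
  }
  # 0-based voxel coordinates of the selected voxels
  i0 <- idx - 1L
  vx <- i0 %% dims[1]
  vy <- (i0 %/% dims[1]) %% dims[2]
  vz <- i0 %/% (dims[1] * dims[2])
  bx <- vx %/% block_shape[1]
  by <- vy %/% block_shape[2]
  bz <- vz %/% block_shape[3]
  nbx <- (dims[1] + block_shape[1] - 1L) %/% block_shape[1]
  nby <- (dims[2] + block_shape[2] - 1L) %/% block_shape[2]
  key <- bx + nbx * (by + nby * bz)
  node <- match(key, sort(unique(key)))
  n <- max(node)
  if (n < 2L) stop("fewer than 2 nodes; use a smaller block_shape")
  cnt <- tabulate(node, n)
  feat <- if (feature_stat == "mean") {
    unname(rowsum(volume$intensities[idx], node)[, 1]) / cnt
  } else {
    # lower median: the summary is always an observed voxel intensity, never
    # an interpolated midpoint between two populations straddling a boundary
    vals <- volume$intensities[idx]
    sv <- vals[order(node, vals)]       # grouped by node, sorted within
    starts <- cumsum(cnt) - cnt + 1L
    sv[starts + (cnt - 1L) %/% 2L]
  }
  cx <- rowsum(as.numeric(vx), node)[, 1] / cnt
  cy <- rowsum(as.numeric(vy), node)[, 1] / cnt
  cz <- rowsum(as.numeric(vz), node)[, 1] / cnt
  grid <- cbind(x = rowsum(bx, node)[, 1] / cnt,
                y = rowsum(by, node)[, 1] / cnt,
                z = rowsum(bz, node)[, 1] / cnt)  # constant per node
  storage.mode(grid) <- "integer"
  centroid <- cbind(x = cx, y = cy, z = cz)
  node_of_voxel <- array(NA_integer_, dims)
  node_of_voxel[idx] <- node
  # In "block" units the positions are the integer block indices themselves:
  # inter-node spacing is then isotropic (~1) regardless of block anisotropy.
  positions <- if (position_units == "block") {
    g <- grid
    storage.mode(g) <- "double"
    g
  } else centroid
  structure(list(features = feat, positions = positions,
                 centroid_voxels = centroid, grid = grid,
                 node_of_voxel = node_of_voxel, block_shape = block_shape,
                 position_units = position_units,
                 feature_stat = feature_stat, n = n),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("Node set: %d nodes, block %s, positions in %s units\n",
              x$n, paste(x$block_shape, collapse = "x"), x$position_units))
  invisible(x)
}

#' Gaussian scale from the range of a distance matrix
#'
#' The scale is 0.15 times the range (max minus min) of the finite
#' off-diagonal distances.
#'
#' @param distances Square matrix of pairwise distances (or any numeric
#'   matrix; the diagonal is ignored).
#' @return Positive scalar scale.
#' @export
estimate_scale <- function(distances) {
  distances <- as.matrix(distances)
  off <- distances[row(distances) != col(distances)]
  off <- off[is.finite(off)]
  if (!length(off)) stop("no finite off-diagonal distances")
  rng <- max(off) - min(off)
  if (rng <= 0) stop("degenerate scale: all distances equal (zero range)")
  0.15 * rng
}

# 0.15-range rule on a seeded subsample of node pairs (used for "auto" scales
# so that no n^2 distance matrix is ever formed).
estimate_scale_sampled <- function(values, n_pairs = 2000L, seed = 1L,
                                   factor = 0.15) {
  n <- nrow(values)
  set.seed(seed)
  m <- as.integer(min(as.numeric(n_pairs), as.numeric(n) * (n - 1) / 2))
  i <- sample.int(n, m, replace = TRUE)
  j <- sample.int(n, m, replace = TRUE)
  keep <- i != j
  d <- sqrt(rowSums((values[i[keep], , drop = FALSE] -
                     values[j[keep], , drop = FALSE])^2))
  rng <- max(d) - min(d)
  if (rng <= 0) stop("degenerate scale: all sampled distances equal")
  factor * rng
}

#' Sparse affinity kernel between graph nodes
#'
#' `k(i, j) = exp(-|F_i - F_j|^2 / (2 sigma_feature^2)) *
#' exp(-|X_i - X_j|^2 / (2 sigma_geo^2))` when the geometric distance is below
#' the radius `r`, and 0 otherwise; the diagonal is 1. The kernel is symmetric
#' and nonnegative by construction.
#'
#' @param nodes A [build_nodes()] result.
#' @param cfg A [diffusion_config()]; `"auto"` scales are estimated by the
#'   0.15-range rule on a seeded subsample of node pairs.
#' @return List of class `sparse_kernel` with the `Matrix::dsCMatrix` kernel
#'   `k` and the scales used.
#' @export
compute_kernel <- function(nodes, cfg = diffusion_config()) {
  stopifnot(inherits(nodes, "node_set"))
  n <- nodes$n
  r <- cfg$radius
  sf <- cfg$sigma_feature
  sg <- cfg$sigma_geo
  ff <- if (is.null(cfg$feature_scale_factor)) 0.15 else cfg$feature_scale_factor
  if (identical(sf, "auto"))
    sf <- estimate_scale_sampled(cbind(nodes$features), seed = cfg$seed,
                                 factor = ff)
  if (identical(sg, "auto"))
    sg <- estimate_scale_sampled(nodes$positions, seed = cfg$seed + 1L)
  stopifnot(is.numeric(sf), sf > 0, is.numeric(sg), sg > 0)

  if (nodes$position_units == "block") {
    pairs <- grid_neighbor_pairs(nodes$grid, r)
  } else {
    if (n > 4000L)
      stop("dense pairwise search not supported for n > 4000; ",
           "use block position units")
    rv <- rep_len(as.numeric(r), 3L)
    d2 <- as.matrix(stats::dist(nodes$positions))^2
    nd2 <- as.matrix(stats::dist(sweep(nodes$positions, 2, rv, `/`)))^2
    sel <- which(upper.tri(d2) & nd2 < 1, arr.ind = TRUE)
    pairs <- list(i = sel[, 1], j = sel[, 2], d2 = d2[sel])
  }
  if (any(tabulate(c(pairs$i, pairs$j), n) == 0L))
    stop("isolated node(s) with no neighbor within radius r; increase r")
  dF2 <- (nodes$features[pairs$i] - nodes$features[pairs$j])^2
  w <- exp(-dF2 / (2 * sf^2)) * exp(-pairs$d2 / (2 * sg^2))
  ii <- pmin(pairs$i, pairs$j)
  jj <- pmax(pairs$i, pairs$j)
  K <- Matrix::sparseMatrix(i = c(ii, seq_len(n)),
                            j = c(jj, seq_len(n)),
                            x = c(w, rep(1, n)),
                            dims = c(n, n), symmetric = TRUE)
  structure(list(k = K, sigma_feature = sf, sigma_geo = sg, radius = r),
            class = "sparse_kernel")
}

# Neighbor pairs among nodes sitting on an integer grid: enumerate the
# half-space of integer offsets inside the (possibly anisotropic) radius --
# sum((d / r)^2) < 1, with scalar `r` recycled to all three axes -- and match
# shifted grid positions through a lookup array. Returns each unordered pair
# once, with squared distances in grid units.
grid_neighbor_pairs <- function(grid, r) {
  rv <- rep_len(as.numeric(r), 3L)
  rr <- ceiling(rv - 1e-9) - 1L
  off <- as.matrix(expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2],
                               dz = -rr[3]:rr[3]))
  d2 <- rowSums(off^2)
  nd2 <- rowSums(sweep(off, 2, rv, `/`)^2)
  keep <- d2 > 0 & nd2 < 1
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  # half-space: lexicographically positive offsets only
  lex <- off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
         (off[, 2] == 0 & off[, 1] > 0)))
  off <- off[lex, , drop = FALSE]
  d2 <- d2[lex]
  gmin <- apply(grid, 2, min)
  g <- sweep(grid, 2, gmin, `-`)
  gd <- apply(g, 2, max) + 1L
  lookup <- array(NA_integer_, gd)
  lookup[g + 1L] <- seq_len(nrow(g))
  ii <- jj <- dd <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    tgt <- sweep(g, 2, off[k, ], `+`)
    ok <- tgt[, 1] >= 0 & tgt[, 1] < gd[1] & tgt[, 2] >= 0 &
      tgt[, 2] < gd[2] & tgt[, 3] >= 0 & tgt[, 3] < gd[3]
    j <- rep(NA_integer_, nrow(g))
    j[ok] <- lookup[tgt[ok, , drop = FALSE] + 1L]
    hit <- which(!is.na(j))
    ii[[k]] <- hit
    jj[[k]] <- j[hit]
    dd[[k]] <- rep(d2[k], length(hit))
  }
  list(i = unlist(ii), j = unlist(jj), d2 = unlist(dd))
}

#' Normalize a kernel into a Markov transition matrix
#'
#' Degrees `s(x) = sum_y k(x, y)`; transition probabilities
#' `p(x, y) = k(x, y) / s(x)`, so every row sums to one.
#'
#' @param kernel A [compute_kernel()] result, or any symmetric nonnegative
#'   matrix.
#' @return List of class `transition_matrix` with row-stochastic `P` and the
#'   degree vector `degrees`.
#' @export
markov_normalize <- function(kernel) {
  K <- if (inherits(kernel, "sparse_kernel")) kernel$k else {
    K0 <- Matrix::Matrix(kernel, sparse = TRUE)
    if (max(abs(K0 - Matrix::t(K0))) > 0) stop("kernel must be symmetric")
    if (min(K0) < 0) stop("kernel must be nonnegative")
    K0
  }
  s <- Matrix::rowSums(K)
  if (any(s <= 0)) stop("zero row sum: node with no affinity at all")
  P <- Matrix::Diagonal(x = 1 / s) %*% K
  structure(list(P = P, degrees = s, n = length(s)),
            class = "transition_matrix")
}

#' Spectral diffusion embedding of a Markov matrix
#'
#' Eigenpairs are computed on the symmetric conjugate
#' `S = D^{1/2} P D^{-1/2}` (same spectrum as `P`) and converted back
#' (`psi = D^{-1/2} v`). The stationary eigenpair (eigenvalue 1, constant
#' eigenvector) is identified and dropped -- on disconnected graphs, where the
#' top eigenvalue is degenerate, the degenerate eigenspace is first rotated so
#' one basis vector aligns exactly with the stationary direction. The `omega`
#' remaining eigenpairs of largest magnitude give coordinates
#' `Psi_tau(i) = (lambda_1^tau psi_1(i), ..., lambda_omega^tau psi_omega(i))`.
#'
#' @param tm A [markov_normalize()] result.
#' @param cfg A [diffusion_config()] supplying `omega`, `tau`, `seed`; or pass
#'   `omega`/`tau` directly.
#' @param omega,tau Override the config values.
#' @return List of class `diffusion_embedding` with `values` (the retained
#'   eigenvalues, decreasing magnitude), `vectors` (n x omega matrix of
#'   psi_i), and `coordinates` (n x omega matrix Psi_tau).
#' @export
diffusion_embed <- function(tm, cfg = diffusion_config(), omega = cfg$omega,
                            tau = cfg$tau) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- tm$n
  omega <- as.integer(omega)
  if (omega >= n) stop("omega must be smaller than the number of nodes")
  dhalf <- sqrt(tm$degrees)
  S <- Matrix::Diagonal(x = dhalf) %*% tm$P %*% Matrix::Diagonal(x = 1 / dhalf)
  S <- (S + Matrix::t(S)) / 2
  nev <- omega + 1L

  if (n <= 1500L) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    ord <- order(abs(es$values), decreasing = TRUE)[seq_len(nev)]
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
  } else {
    # Shift-invert Lanczos about sigma just above 1: the top of the spectrum
    # of S is often a tight near-degenerate cluster at 1 (one eigenvalue per
    # weakly coupled region), which plain largest-magnitude Lanczos resolves
    # extremely slowly; mapping lambda -> 1/(lambda - sigma) spreads the
    # cluster apart and converges in a few factorized solves.
    set.seed(cfg$seed)
    res <- tryCatch(
      RSpectra::eigs_sym(S, k = nev, sigma = 1 + 1e-6,
                         opts = list(maxitr = 5000L)),
      error = function(e) stop("eigensolver failed to converge: ",
                               conditionMessage(e)))
    ord <- order(abs(res$values), decreasing = TRUE)
    vals <- res$values[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }

  # Rotate the (possibly degenerate) top eigenspace so its first basis vector
  # is the stationary direction D^{1/2} 1, then drop that vector.
  u <- dhalf / sqrt(sum(dhalf^2))
  lmax <- max(vals)
  top <- which(vals > lmax - 1e-8)
  cc <- crossprod(vecs[, top, drop = FALSE], u)
  if (sqrt(sum(cc^2)) > 1e-6 && length(top) >= 1L) {
    Q <- qr.Q(qr(cbind(cc, diag(length(top))[, -which.max(abs(cc)),
                                             drop = FALSE])))
    vecs[, top] <- vecs[, top, drop = FALSE] %*% Q
    drop_idx <- top[1]
  } else {
    drop_idx <- which.max(vals)
  }
  keep <- setdiff(seq_len(nev), drop_idx)[seq_len(omega)]
  vals_k <- vals[keep]
  vecs_k <- vecs[, keep, drop = FALSE]
  if (any(abs(vals_k) > 1 + 1e-9))
    stop("retained eigenvalue magnitude exceeds 1")
  psi <- vecs_k / dhalf
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(psi))) {
    m <- which.max(abs(psi[, j]))
    if (psi[m, j] < 0) {
      psi[, j] <- -psi[, j]
      vecs_k[, j] <- -vecs_k[, j]
    }
  }
  coords <- sweep(psi, 2, vals_k^tau, `*`)
  structure(list(values = vals_k, vectors = psi, coordinates = coords,
                 omega = omega, tau = tau),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("Diffusion embedding: %d coordinates, tau = %d\n",
              x$omega, x$tau))
  cat("  eigenvalues:", paste(sprintf("%.4f", x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Cluster nodes in diffusion-embedding space
#'
#' Seeded k-means (10 random restarts, lowest within-cluster sum of squares
#' kept) on the `Psi_tau` coordinates.
#'
#' @param embedding A [diffusion_embed()] result.
#' @param n_clusters Number of clusters (at most the number of nodes).
#' @param seed Integer seed; reruns with the same seed are identical.
#' @return Integer label vector (values `1..n_clusters`).
#' @export
cluster_embedding <- function(embedding, n_clusters, seed = 1L) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  X <- embedding$coordinates
  n <- nrow(X)
  if (n_clusters > n) stop("n_clusters exceeds the number of nodes")
  if (n_clusters == 1L) return(rep(1L, n))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = n_clusters, nstart = 10L,
                                       iter.max = 200L))
  as.integer(km$cluster)
}
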