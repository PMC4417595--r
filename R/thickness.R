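# Per-layer and total thickness maps in micrometers; foveal center location.

#' Compute per-layer and total thickness maps
#'
#' Layer `L` thickness at `(x, z)` is `(depth[L+1] - depth[L]) *
#' axial_spacing_um`; the total map is the elementwise sum of the 11 layer
#' maps (exactly, by construction).
#'
#' @param surfaces A [surface_set] (or `retinal_segmentation`).
#' @param axial_spacing_um Micrometers per axial voxel (use 1 for voxel-unit
#'   maps).
#' @param lateral_spacing_um Optional `(x, z)` micrometers per pixel, carried
#'   along for sector analysis.
#' @return Object of class `thickness_maps`: `per_layer` (nx x nz x 11 array,
#'   um), `total` (nx x nz), `layer_names`, `lateral_spacing_um`.
#' @export
compute_thickness_maps <- function(surfaces, axial_spacing_um,
                                   lateral_spacing_um = NULL) {
  if (inherits(surfaces, "retinal_segmentation")) surfaces <- surfaces$surfaces
  stopifnot(inherits(surfaces, "surface_set"), axial_spacing_um > 0)
  d <- surfaces$depths
  per_layer <- (d[, , 2:12, drop = FALSE] - d[, , 1:11, drop = FALSE]) *
    axial_spacing_um
  per_layer <- pmax(per_layer, 0)   # ordering invariant makes this a no-op
  total <- apply(per_layer, c(1, 2), sum)
  structure(list(per_layer = per_layer, total = total,
                 layer_names = surfaces$layer_names,
                 axial_spacing_um = axial_spacing_um,
                 lateral_spacing_um = lateral_spacing_um),
            class = "thickness_maps")
}

#' @export
print.thickness_maps <- function(x, ...) {
  d <- dim(x$per_layer)
  cat(sprintf("Thickness maps: 11 layers + total on a %d x %d grid (um)\n",
              d[1], d[2]))
  mu <- apply(x$per_layer, 3, mean)
  for (l in 1:11)
    cat(sprintf("  %-12s mean %6.1f um\n", x$layer_names[l], mu[l]))
  cat(sprintf("  %-12s mean %6.1f um\n", "total", mean(x$total)))
  invisible(x)
}

#' Plot a thickness map in pseudo color
#'
#' @param x A `thickness_maps` object.
#' @param layer Layer index 1..11, or `"total"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.thickness_maps <- function(x, layer = "total", ...) {
  m <- if (identical(layer, "total")) x$total else x$per_layer[, , layer]
  nm <- if (identical(layer, "total")) "total retina" else x$layer_names[layer]
  image(m, col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
        xlab = "x (lateral)", ylab = "z (B-scan)", useRaster = TRUE, ...)
  title(sprintf("%s thickness (%.0f-%.0f um)", nm, min(m), max(m)))
  invisible(x)
}

# 2D mean filter with odd window; partial windows at the border (mean of the
# available in-window pixels).
mean_filter2 <- function(mat, window) {
  if (window <= 1L) return(mat)
  h <- (window - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr
    ok_c <- cs >= 1L & cs <= nc
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + mat[rs[ok_r], cs[ok_c]]
    cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
  }
  acc / cnt
}

#' Locate the foveal center on the RNFL thickness map
#'
#' The fovea is the minimum of the mean-filtered nerve-fiber-layer thickness
#' map. Ties are broken by proximity to the grid center, then
#' lexicographically (x before z); a constant map therefore returns the grid
#' center.
#'
#' @param rnfl_map Matrix (x, z) of layer-1 thickness.
#' @param smooth_window Odd mean-filter window (default 5).
#' @return Integer `(x, z)` 0-based index of the foveal center.
#' @export
locate_fovea <- function(rnfl_map, smooth_window = 5L) {
  stopifnot(is.matrix(rnfl_map))
  if (any(dim(rnfl_map) < smooth_window))
    stop("map smaller than the smoothing window")
  sm <- mean_filter2(rnfl_map, smooth_window)
  mn <- min(sm)
  cand <- which(sm <= mn + 1e-12, arr.ind = TRUE)
  ctr <- (dim(rnfl_map) + 1) / 2
  d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
  best <- which(d2 == min(d2))
  # lexicographic tie-break: smallest x, then smallest z
  bestc <- cand[best, , drop = FALSE]
  ordp <- order(bestc[, 1], bestc[, 2])[1]
  as.integer(bestc[ordp, ] - 1L)
}

#' Write thickness maps to CSV grids and pseudo-color PNGs
#'
#' Writes one CSV (x rows, z columns, um) and one PNG per layer plus the
#' total-retina map into `dir`.
#'
#' @param maps A `thickness_maps` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_thickness_outputs <- function(maps, dir) {
  stopifnot(inherits(maps, "thickness_maps"))
  if (any(!is.finite(maps$per_layer)) || any(maps$per_layer < 0))
    stop("validation error: thickness maps must be finite and nonnegative")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9]+", "_", maps$layer_names)
  all_maps <- c(lapply(1:11, function(l) maps$per_layer[, , l]),
                list(maps$total))
  names(all_maps) <- c(sprintf("layer%02d_%s", 1:11, safe), "total")
  pal <- grDevices::hcl.colors(256, "Spectral", rev = TRUE)
  for (nm in names(all_maps)) {
    m <- all_maps[[nm]]
    write.table(m, file.path(dir, paste0(nm, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE)
    rng <- range(m)
    idx <- if (rng[2] > rng[1])
      1L + floor(255 * (m - rng[1]) / (rng[2] - rng[1])) else
      matrix(1L, nrow(m), ncol(m))
    rgb <- grDevices::col2rgb(pal[idx]) / 255
    img <- array(0, c(ncol(m), nrow(m), 3))  # PNG rows = z, cols = x
    for (ch in 1:3)
      img[, , ch] <- t(matrix(rgb[ch, ], nrow(m), ncol(m)))
    png::writePNG(img, file.path(dir, paste0(nm, ".png")))
  }
  invisible(dir)
}
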