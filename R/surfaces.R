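# Surface sets: twelve ordered axial depth maps bounding eleven layers.

#' Construct a set of twelve retinal surfaces
#'
#' @param depths Numeric array of dimension `c(nx, nz, 12)`: for each lateral
#'   position `(x, z)` the 0-based axial depth (in voxel units, real-valued)
#'   of surfaces 1..12, ordered from the vitreous side downward. Surface `s`
#'   and `s+1` bound layer `s`.
#' @param layer_names Character vector of the 11 layer names bounded by the
#'   surfaces; defaults to [retinal_layer_names()].
#' @param axial_extent Optional number of axial voxels; when given, depths
#'   must lie in `[0, axial_extent]`.
#' @return Object of class `surface_set`.
#' @export
surface_set <- function(depths, layer_names = retinal_layer_names(),
                        axial_extent = NULL) {
  if (!is.array(depths) || length(dim(depths)) != 3L || dim(depths)[3] != 12L)
    stop("'depths' must be an nx x nz x 12 array")
  if (length(layer_names) != 11L)
    stop("'layer_names' must have length 11")
  if (any(!is.finite(depths))) stop("surface depths must be finite")
  if (any(depths < 0)) stop("validation error: negative surface depth")
  if (!is.null(axial_extent) && any(depths > axial_extent))
    stop("validation error: surface depth beyond axial extent")
  gaps <- depths[, , 2:12, drop = FALSE] - depths[, , 1:11, drop = FALSE]
  if (any(gaps < -1e-9))
    stop("validation error: surfaces out of depth order (crossing)")
  structure(list(depths = depths, layer_names = layer_names,
                 axial_extent = axial_extent),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x$depths)
  cat(sprintf("Surface set: 12 surfaces on a %d x %d (x, z) grid\n", d[1], d[2]))
  cat(sprintf("  depth range: [%.2f, %.2f] voxels\n",
              min(x$depths), max(x$depths)))
  cat("  layers:", paste(x$layer_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write surfaces to a TSV file (plus JSON header)
#'
#' Long-form TSV with columns `surface_index` (1..12), `x`, `z` (0-based) and
#' `depth_voxels`; layer names and grid dimensions go to `<path>.json`.
#'
#' @param surfaces A [surface_set].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  d <- dim(surfaces$depths)
  grid <- expand.grid(x = seq_len(d[1]) - 1L, z = seq_len(d[2]) - 1L,
                      surface_index = 1:12)
  df <- data.frame(surface_index = grid$surface_index, x = grid$x, z = grid$z,
                   depth_voxels = as.vector(surfaces$depths))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(layer_names = surfaces$layer_names,
                            nx = d[1], nz = d[2],
                            axial_extent = surfaces$axial_extent),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read surfaces written by [write_surfaces()]
#'
#' Validates the depth-ordering invariant; a file whose surfaces cross raises
#' a validation error.
#'
#' @param path TSV path.
#' @return A [surface_set].
#' @export
read_surfaces <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  need <- c("surface_index", "x", "z", "depth_voxels")
  if (!all(need %in% names(df)))
    stop("format error: surface TSV missing columns")
  hdr_path <- paste0(path, ".json")
  hdr <- if (file.exists(hdr_path)) read_sidecar(hdr_path) else list()
  nx <- if (!is.null(hdr$nx)) hdr$nx else max(df$x) + 1L
  nz <- if (!is.null(hdr$nz)) hdr$nz else max(df$z) + 1L
  depths <- array(NA_real_, c(nx, nz, 12))
  depths[cbind(df$x + 1L, df$z + 1L, df$surface_index)] <- df$depth_voxels
  if (any(!is.finite(depths)))
    stop("format error: incomplete surface grid")
  surface_set(depths,
              layer_names = if (!is.null(hdr$layer_names))
                unlist(hdr$layer_names) else retinal_layer_names(),
              axial_extent = hdr$axial_extent)
}

#' Border positioning errors between estimated and reference surfaces
#'
#' @param result A [surface_set] or a `retinal_segmentation` (its surfaces
#'   are used).
#' @param truth Reference [surface_set] on the same grid.
#' @param axial_spacing_um Micrometers per axial voxel; use 1 for voxel-unit
#'   errors.
#' @return Data frame with one row per surface: `surface`, `unsigned_um`
#'   (mean absolute error) and `signed_um` (mean error, estimated minus
#'   reference).
#' @export
surface_errors <- function(result, truth, axial_spacing_um = 1) {
  est <- if (inherits(result, "retinal_segmentation")) result$surfaces else result
  stopifnot(inherits(est, "surface_set"), inherits(truth, "surface_set"))
  if (!identical(dim(est$depths), dim(truth$depths)))
    stop("surface grids are not congruent")
  diffs <- (est$depths - truth$depths) * axial_spacing_um
  data.frame(surface = 1:12,
             unsigned_um = apply(abs(diffs), 3, mean),
             signed_um = apply(diffs, 3, mean))
}
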