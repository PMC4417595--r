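# OCT volume container and file I/O.
#
# Axis convention (fixed here, relied on by every other module):
# intensities[x, y, z] with x lateral, y axial (depth increases downward,
# vitreous at y = 0), z the B-scan index. Indices are 0-based wherever a
# position is reported (surface depths, fovea location).

#' Construct an OCT volume
#'
#' Wraps a 3D intensity array together with voxel spacing, eye side and
#' optional subject metadata. Intensities are brought to `[0, 1]`: arrays with
#' values outside that range are min-max rescaled; arrays already inside it are
#' kept unchanged so that write/read round trips are lossless.
#'
#' @param intensities 3D numeric array indexed `[x, y, z]` (x lateral, y axial
#'   top-to-bottom, z B-scan). Every dimension must be at least 2.
#' @param spacing_um Numeric length-3 vector, micrometers per voxel along
#'   x, y, z. All entries must be positive.
#' @param eye_side `"OD"` (right) or `"OS"` (left).
#' @param subject_meta Optional list with elements `age` (years) and `sex`
#'   (`"M"` or `"F"`).
#' @param normalize Logical; if `TRUE` (default) rescale to `[0, 1]` when
#'   values fall outside that range. A constant array is rejected.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, spacing_um, eye_side = c("OD", "OS"),
                       subject_meta = NULL, normalize = TRUE) {
  eye_side <- match.arg(eye_side)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array [x, y, z]")
  if (any(dim(intensities) < 2L))
    stop("every volume dimension must be at least 2")
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("configuration error: 'spacing_um' must be 3 positive numbers")
  rng <- range(intensities)
  if (rng[1] == rng[2])
    stop("degenerate input: volume is constant (max = min)")
  if (normalize && (rng[1] < 0 || rng[2] > 1)) {
    intensities <- (intensities - rng[1]) / (rng[2] - rng[1])
  } else if (rng[1] < 0 || rng[2] > 1) {
    stop("intensities outside [0, 1] and normalize = FALSE")
  }
  structure(list(intensities = intensities,
                 spacing_um = spacing_um,
                 eye_side = eye_side,
                 subject_meta = subject_meta),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("OCT volume: %d x %d x %d voxels (x lateral, y axial, z B-scan)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  voxel spacing: %.3g x %.3g x %.3g um, eye: %s\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3], x$eye_side))
  cat(sprintf("  intensity range: [%.4f, %.4f]\n",
              min(x$intensities), max(x$intensities)))
  if (!is.null(x$subject_meta))
    cat(sprintf("  subject: age %s, sex %s\n",
                format(x$subject_meta$age), format(x$subject_meta$sex)))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensities)

# Locate the JSON sidecar for a volume file.
sidecar_path <- function(path, metadata_path = NULL) {
  if (!is.null(metadata_path)) return(metadata_path)
  cands <- c(paste0(path, ".json"), sub("\\.[^.]+(\\.gz)?$", ".json", path))
  hit <- cands[file.exists(cands)]
  if (length(hit)) hit[1] else NA_character_
}

read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(meta$spacing_um)) meta$spacing_um <- as.numeric(meta$spacing_um)
  meta
}

#' Read an OCT volume from disk
#'
#' Supported formats: multi-page TIFF (one page per B-scan, rows = axial,
#' columns = lateral), NIfTI (`.nii` / `.nii.gz`, voxel dimensions interpreted
#' as micrometers), and raw float32 (`.raw` / `.bin`) with a JSON sidecar.
#' The sidecar (`<file>.json`, or `metadata_path`) carries `spacing_um`,
#' `eye_side`, optional `age`/`sex`, and for raw files the array `shape`.
#' Voxel spacing must be available from the sidecar (or NIfTI header);
#' it is never guessed.
#'
#' @param path Path to the volume file.
#' @param metadata_path Optional explicit path to the JSON sidecar.
#' @return An [oct_volume].
#' @export
read_volume <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  ext <- tolower(sub("^.*?(\\.[^.]+(\\.gz)?)$", "\\1", basename(path)))
  sc <- sidecar_path(path, metadata_path)
  meta <- if (!is.na(sc) && file.exists(sc)) read_sidecar(sc) else list()

  arr <- if (ext %in% c(".tif", ".tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("format error reading TIFF: ",
                                               conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
      t(p)                                      # page [y, x] -> [x, y]
    })
    array(unlist(pages, use.names = FALSE),
          dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  } else if (ext %in% c(".nii", ".nii.gz")) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("format error reading NIfTI: ",
                                             conditionMessage(e)))
    if (is.null(meta$spacing_um))
      meta$spacing_um <- as.numeric(RNifti::pixdim(img))[1:3]
    array(as.numeric(img), dim = dim(img)[1:3])   # plain array, no NIfTI attrs
  } else if (ext %in% c(".raw", ".bin")) {
    if (is.null(meta$shape))
      stop("configuration error: raw volume needs 'shape' in its JSON sidecar")
    shp <- as.integer(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = prod(shp), size = 4L)
    if (length(vals) != prod(shp))
      stop("format error: raw file shorter than sidecar shape implies")
    array(vals, dim = shp)
  } else {
    stop("format error: unsupported volume format '", ext, "'")
  }

  if (is.null(meta$spacing_um))
    stop("configuration error: voxel spacing_um not found in sidecar/header; ",
         "refusing to guess")
  subject_meta <- NULL
  if (!is.null(meta$age) || !is.null(meta$sex))
    subject_meta <- list(age = meta$age, sex = meta$sex)
  oct_volume(arr, spacing_um = meta$spacing_um,
             eye_side = if (is.null(meta$eye_side)) "OD" else meta$eye_side,
             subject_meta = subject_meta)
}

#' Write an OCT volume to disk
#'
#' Writes TIFF (32-bit float, one page per B-scan), NIfTI, or raw float32
#' according to the file extension, plus a JSON sidecar (`<file>.json`) with
#' spacing, eye side, shape and subject metadata.
#'
#' @param volume An [oct_volume].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  arr <- volume$intensities
  ext <- tolower(sub("^.*?(\\.[^.]+(\\.gz)?)$", "\\1", basename(path)))
  if (ext %in% c(".tif", ".tiff")) {
    pages <- lapply(seq_len(dim(arr)[3]), function(z) t(arr[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume$spacing_um
    RNifti::writeNifti(img, path)
  } else if (ext %in% c(".raw", ".bin")) {
    con <- file(path, "wb")
    writeBin(as.numeric(arr), con, size = 4L)
    close(con)
  } else {
    stop("format error: unsupported volume format '", ext, "'")
  }
  meta <- list(spacing_um = volume$spacing_um, eye_side = volume$eye_side,
               shape = dim(arr))
  if (!is.null(volume$subject_meta)) {
    meta$age <- volume$subject_meta$age
    meta$sex <- volume$subject_meta$sex
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
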