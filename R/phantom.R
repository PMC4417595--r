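# Synthetic layered OCT phantoms with known 12-surface ground truth, and
# synthetic cohorts with programmable age/sex thickness effects.

#' Phantom configuration
#'
#' Defaults describe a normal macular volume at desk scale: 11 layers with
#' anatomically plausible thicknesses (total 345 um), alternating bright/dark
#' reflectivities (bright NFL/IPL/CL/RPE, dark ONL), a Gaussian foveal pit
#' thinning the inner layers (1-4), smooth low-frequency surface undulation,
#' and multiplicative log-normal speckle.
#'
#' @param shape Integer `(nx, ny, nz)` voxel dimensions.
#' @param spacing_um Micrometers per voxel along x, y, z.
#' @param base_depth_um Depth of surface 1 (the vitreous/NFL border) at the
#'   periphery, in micrometers.
#' @param layer_thickness_um 11 nonnegative layer thicknesses in micrometers
#'   (away from the pit).
#' @param layer_reflectivity 11 reflectivities in `[0, 1]`.
#' @param vitreous_reflectivity,subrpe_reflectivity Reflectivity above surface
#'   1 and below surface 12.
#' @param pit_depth_um,pit_radius_um Gaussian foveal pit: total thickness
#'   removed at the pit center and the Gaussian sigma of its radial profile.
#' @param pit_layers Indices of the layers thinned by the pit (default 1:4).
#' @param undulation_amplitude_um,undulation_length_um Amplitude (SD) and
#'   correlation length of the smooth random undulation added to the base
#'   surface.
#' @param speckle_sigma Log-normal speckle sigma (0 disables noise).
#' @param noise_model `"speckle"` (multiplicative log-normal, mean 1) or
#'   `"gaussian"` (additive).
#' @param eye_side `"OD"` or `"OS"` (OS phantoms are mirrored in x).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 128L, 16L),
                           spacing_um = c(94, 3.87, 400),
                           base_depth_um = 80,
                           layer_thickness_um = c(30, 35, 35, 32, 25, 80,
                                                  25, 15, 25, 15, 28),
                           layer_reflectivity = c(0.75, 0.45, 0.65, 0.35,
                                                  0.60, 0.15, 0.50, 0.70,
                                                  0.30, 0.55, 0.85),
                           vitreous_reflectivity = 0.05,
                           subrpe_reflectivity = 0.10,
                           pit_depth_um = 100, pit_radius_um = 600,
                           pit_layers = 1:4,
                           undulation_amplitude_um = 8,
                           undulation_length_um = 1500,
                           speckle_sigma = 0.1,
                           noise_model = c("speckle", "gaussian"),
                           eye_side = c("OD", "OS"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  eye_side <- match.arg(eye_side)
  stopifnot(length(shape) == 3L, all(shape >= 2L),
            length(layer_thickness_um) == 11L, all(layer_thickness_um >= 0),
            length(layer_reflectivity) == 11L,
            all(layer_reflectivity >= 0 & layer_reflectivity <= 1),
            speckle_sigma >= 0, pit_depth_um >= 0, pit_radius_um > 0)
  structure(list(shape = as.integer(shape), spacing_um = spacing_um,
                 base_depth_um = base_depth_um,
                 layer_thickness_um = layer_thickness_um,
                 layer_reflectivity = layer_reflectivity,
                 vitreous_reflectivity = vitreous_reflectivity,
                 subrpe_reflectivity = subrpe_reflectivity,
                 pit_depth_um = pit_depth_um, pit_radius_um = pit_radius_um,
                 pit_layers = pit_layers,
                 undulation_amplitude_um = undulation_amplitude_um,
                 undulation_length_um = undulation_length_um,
                 speckle_sigma = speckle_sigma, noise_model = noise_model,
                 eye_side = eye_side, seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth zero-mean random field on an (nx, nz) lateral grid: coarse white
# noise bilinearly upsampled, scaled to unit SD. Correlation length is set by
# the coarse-grid pitch.
smooth_field <- function(nx, nz, length_px_x, length_px_z) {
  cx <- max(2L, ceiling(nx / max(length_px_x, 1)) + 1L)
  cz <- max(2L, ceiling(nz / max(length_px_z, 1)) + 1L)
  coarse <- matrix(rnorm(cx * cz), cx, cz)
  xi <- seq(1, cx, length.out = nx)
  zi <- seq(1, cz, length.out = nz)
  x0 <- pmin(floor(xi), cx - 1L); fx <- xi - x0
  z0 <- pmin(floor(zi), cz - 1L); fz <- zi - z0
  f <- outer(seq_len(nx), seq_len(nz), function(i, j) {
    a <- coarse[cbind(x0[i], z0[j])] * (1 - fx[i]) * (1 - fz[j]) +
      coarse[cbind(x0[i] + 1L, z0[j])] * fx[i] * (1 - fz[j]) +
      coarse[cbind(x0[i], z0[j] + 1L)] * (1 - fx[i]) * fz[j] +
      coarse[cbind(x0[i] + 1L, z0[j] + 1L)] * fx[i] * fz[j]
    a
  })
  s <- sd(f)
  if (s > 0) f / s else f
}

# Ground-truth thickness field (um): nx x nz x 11.
phantom_thickness_field <- function(cfg) {
  nx <- cfg$shape[1]; nz <- cfg$shape[3]
  xc <- (seq_len(nx) - 1 - (nx - 1) / 2) * cfg$spacing_um[1]
  zc <- (seq_len(nz) - 1 - (nz - 1) / 2) * cfg$spacing_um[3]
  rho2 <- outer(xc^2, zc^2, `+`)
  pit <- cfg$pit_depth_um * exp(-rho2 / (2 * cfg$pit_radius_um^2))
  th <- array(rep(cfg$layer_thickness_um, each = nx * nz), c(nx, nz, 11))
  w <- cfg$layer_thickness_um[cfg$pit_layers]
  # zero-thickness pit layers: nothing to thin, the pit has no effect
  w <- if (sum(w) > 0) w / sum(w) else rep(0, length(w))
  for (k in seq_along(cfg$pit_layers))
    th[, , cfg$pit_layers[k]] <-
      pmax(th[, , cfg$pit_layers[k]] - pit * w[k], 0)
  th
}

#' Generate a synthetic layered OCT phantom
#'
#' Builds smooth ground-truth surfaces (base depth + low-frequency undulation,
#' with a Gaussian foveal pit subtracted from the configured inner layers),
#' fills each inter-surface region with its layer reflectivity, applies
#' multiplicative log-normal speckle (mean 1) or additive Gaussian noise, and
#' clips to `[0, 1]`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @return List with `volume` (an [oct_volume]), `truth` (a [surface_set] of
#'   the 12 real-valued ground-truth surfaces), and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  nx <- cfg$shape[1]; ny <- cfg$shape[2]; nz <- cfg$shape[3]
  depths <- phantom_truth_depths(cfg)

  # voxel y (0-based) belongs to layer s iff depth[s] <= y < depth[s+1];
  # label 0 = vitreous, 12 = below the RPE/BM.
  refl <- c(cfg$vitreous_reflectivity, cfg$layer_reflectivity,
            cfg$subrpe_reflectivity)
  vol <- array(0, c(nx, ny, nz))
  yv <- seq_len(ny) - 1L
  for (z in seq_len(nz)) {
    lay <- matrix(0L, nx, ny)
    for (s in 1:12)
      lay <- lay + (outer(depths[, z, s], yv, `<=`))
    vol[, , z] <- matrix(refl[lay + 1L], nx, ny)
  }
  if (cfg$speckle_sigma > 0) {
    if (cfg$noise_model == "speckle") {
      noise <- exp(rnorm(length(vol), -cfg$speckle_sigma^2 / 2,
                         cfg$speckle_sigma))
      vol <- vol * noise
    } else {
      vol <- vol + rnorm(length(vol), 0, cfg$speckle_sigma)
    }
    vol <- pmin(pmax(vol, 0), 1)
    dim(vol) <- c(nx, ny, nz)
  }
  if (cfg$eye_side == "OS") {
    vol <- vol[nx:1, , , drop = FALSE]
    depths <- depths[nx:1, , , drop = FALSE]
  }
  list(volume = oct_volume(vol, spacing_um = cfg$spacing_um,
                           eye_side = cfg$eye_side, normalize = FALSE),
       truth = surface_set(depths, axial_extent = ny),
       config = cfg)
}

#' Cohort configuration for synthetic normative studies
#'
#' @param n_subjects Number of subjects.
#' @param age_range Ages are drawn uniformly from this range (years).
#' @param sex_ratio Probability of a subject being male.
#' @param age_slope_um_per_year Programmed change of total retinal thickness
#'   per year of age (negative = thinning).
#' @param sex_offset_um Programmed additive total-thickness offset of men
#'   relative to women.
#' @param between_subject_sd_um Between-subject SD of total thickness.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L, age_range = c(18, 89),
                          sex_ratio = 0.5, age_slope_um_per_year = -0.3,
                          sex_offset_um = 8, between_subject_sd_um = 10,
                          seed = 1L) {
  stopifnot(n_subjects >= 1L, between_subject_sd_um >= 0,
            sex_ratio >= 0, sex_ratio <= 1)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 sex_ratio = sex_ratio,
                 age_slope_um_per_year = age_slope_um_per_year,
                 sex_offset_um = sex_offset_um,
                 between_subject_sd_um = between_subject_sd_um,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of phantoms
#'
#' Per subject: draws age and sex, perturbs the total retinal thickness by the
#' programmed age slope (relative to the mid-age), sex offset and
#' between-subject noise -- scaling all 11 layer thicknesses proportionally --
#' and alternates OD/OS eyes (OS volumes mirrored in x). Layer thicknesses
#' that would go negative are clipped at zero with a warning.
#'
#' @param cfg A [cohort_config()].
#' @param phantom_cfg Base [phantom_config()] shared by all subjects.
#' @param volumes If `FALSE` (default) only ground-truth surfaces are built,
#'   which is much faster; set `TRUE` to also simulate the noisy volumes.
#' @return List with `subjects` (each: `truth`, optional `volume`, `age`,
#'   `sex`, `eye_side`, `config`) and `manifest` (data frame).
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            phantom_cfg = phantom_config(),
                            volumes = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  ages <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sexes <- ifelse(runif(n) < cfg$sex_ratio, "M", "F")
  eyes <- rep(c("OD", "OS"), length.out = n)
  mid_age <- mean(cfg$age_range)
  base_total <- sum(phantom_cfg$layer_thickness_um)
  noise <- rnorm(n, 0, cfg$between_subject_sd_um)
  clipped <- FALSE
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    delta <- cfg$age_slope_um_per_year * (ages[i] - mid_age) +
      cfg$sex_offset_um * (sexes[i] == "M") + noise[i]
    scl <- (base_total + delta) / base_total
    thick <- phantom_cfg$layer_thickness_um * scl
    if (any(thick < 0)) {
      thick <- pmax(thick, 0)
      clipped <- TRUE
    }
    pc <- phantom_cfg
    pc$layer_thickness_um <- thick
    pc$eye_side <- eyes[i]
    pc$seed <- cfg$seed + i
    ph <- if (volumes) generate_phantom(pc) else {
      # truth only: no voxel filling, no noise
      pc0 <- pc
      pc0$speckle_sigma <- 0
      truth_only(pc0)
    }
    subjects[[i]] <- list(truth = ph$truth,
                          volume = if (volumes) ph$volume else NULL,
                          age = ages[i], sex = sexes[i], eye_side = eyes[i],
                          config = pc)
  }
  if (clipped)
    warning("some programmed layer thicknesses were negative and were ",
            "clipped at 0")
  manifest <- data.frame(subject = seq_len(n), age = ages, sex = sexes,
                         eye_side = eyes,
                         total_thickness_um = vapply(subjects, function(s) {
                           d <- s$truth$depths
                           mean(d[, , 12] - d[, , 1]) * phantom_cfg$spacing_um[2]
                         }, numeric(1)))
  list(subjects = subjects, manifest = manifest)
}

# Unmirrored ground-truth surfaces (consumes RNG for the undulation field;
# callers seed first). 0-based, real-valued voxel units.
phantom_truth_depths <- function(cfg) {
  nx <- cfg$shape[1]; ny <- cfg$shape[2]; nz <- cfg$shape[3]
  sy <- cfg$spacing_um[2]
  und <- smooth_field(nx, nz,
                      cfg$undulation_length_um / cfg$spacing_um[1],
                      cfg$undulation_length_um / cfg$spacing_um[3]) *
    cfg$undulation_amplitude_um
  th <- phantom_thickness_field(cfg)
  # anchor the smooth outer surface (RPE/BM bottom) and build upward, so the
  # foveal pit appears as a dip of the inner surfaces, as in real retinas
  depths <- array(NA_real_, c(nx, nz, 12))
  depths[, , 12] <- (cfg$base_depth_um + sum(cfg$layer_thickness_um) + und) / sy
  for (s in 11:1)
    depths[, , s] <- depths[, , s + 1] - th[, , s] / sy
  if (min(depths[, , 1]) < 0)
    depths <- depths - min(depths[, , 1])
  if (max(depths[, , 12]) >= ny)
    stop("layers exceed the axial extent; enlarge ny or shrink thicknesses")
  depths
}

# Ground-truth surfaces only (no voxel filling, no noise).
truth_only <- function(cfg) {
  set.seed(cfg$seed)
  depths <- phantom_truth_depths(cfg)
  if (cfg$eye_side == "OS")
    depths <- depths[cfg$shape[1]:1, , , drop = FALSE]
  list(truth = surface_set(depths, axial_extent = cfg$shape[2]), config = cfg)
}
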