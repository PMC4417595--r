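# retidiff

Diffusion-map segmentation and thickness mapping of intraretinal layers in
macular SD-OCT volumes — pure R, with a synthetic phantom so every stage is
testable without clinical data.

`retidiff` segments a 3-D OCT volume into the twelve surfaces bounding eleven
retinal layers, converts them into per-layer and total thickness maps in
micrometers, locates the fovea, aggregates thickness over the nine ETDRS
macular sectors (with right/left-eye mirroring), and tests cohort thickness
against age and sex.

## How it works

Voxels are pooled into graph nodes (block averaging/medians); nodes are joined
by a sparse product Gaussian kernel over intensity difference and geometric
distance, gated by a neighborhood radius; the kernel is normalized into a
row-stochastic Markov matrix whose leading eigenpairs give a low-dimensional
diffusion embedding; k-means clustering in the embedding does the rest.
Segmentation runs in two stages:

1. **Coarse partition** — cluster the whole volume into vitreous / retinal
   band / sub-RPE and keep the band.
2. **Layer localization** — denoise, flatten the band, re-pool at fine axial
   resolution, embed with a sharper intensity scale, drop localized
   (spike) eigenmodes by a participation-ratio filter, cluster into 13
   depth-ordered groups, and read the 12 surfaces off the cluster boundaries
   by a per-column counting rule, followed by median smoothing and an
   isotonic projection that enforces surface ordering exactly.

See the methods vignette (`vignettes/retidiff-methods.Rmd`) for the model,
the design decisions, and validation results.

## Coordinate convention

Fixed across the whole package and all file formats:

* Arrays are indexed `[x, y, z]`: **x** lateral (within a B-scan), **y**
  axial with depth increasing downward (vitreous at `y = 0`), **z** the
  B-scan index.
* All reported positions — surface depths, the fovea location — are
  **0-based**. A surface depth of `d` means the interface sits `d` voxels
  below the top of the scan.
* Intensities live in `[0, 1]` (volumes are min-max normalized on input).
* Physical units are always micrometers, supplied as per-voxel spacing
  `(x, y, z)`; the package refuses to guess a missing spacing.
* NIfTI voxel dimensions are read and written in micrometers (this package's
  convention); override via a JSON sidecar for mm-unit files.

## Quick start (R)

```r
library(retidiff)

# Synthetic ground truth: 11-layer phantom with foveal pit and speckle noise
ph  <- generate_phantom(phantom_config())        # 64 x 128 x 16, sigma = 0.1

# Segment: 12 ordered surfaces + quality diagnostics
res <- segment_volume(ph$volume, seed = 1)
summary(res)
surface_errors(res, ph$truth)                    # vs known truth, in voxels

# Thickness maps (um) and fovea
maps <- compute_thickness_maps(res, axial_spacing_um = ph$volume$spacing_um[2])
plot(maps, layer = "total")
fovea <- locate_fovea(maps$per_layer[, , 1])     # min of the layer-1 map

# ETDRS sectors and cohort statistics
g   <- sector_grid(dim(maps$total), fovea,
                   ph$volume$spacing_um[c(1, 3)], ph$volume$eye_side)
tab <- sector_table(maps, g)                     # mean/SD per layer x sector

co   <- generate_cohort(cohort_config(n_subjects = 60),
                        phantom_config(shape = c(32L, 160L, 8L)))
tabs <- lapply(co$subjects, function(s)
  sector_table(compute_thickness_maps(s$truth, 3.87), g))
cohort_report(tabs, co$manifest$age, co$manifest$sex)
```

## Command line

```sh
retidiff phantom   --seed 1 --out ph/                       # TIFF + truth TSV
retidiff segment   ph/phantom.tif --out seg/                # surfaces.tsv
retidiff thickness seg/surfaces.tsv --axial-spacing-um 3.87 --out thick/
retidiff sectors   seg/surfaces.tsv --axial-spacing-um 3.87 \
                   --lateral-spacing-um 94,400 --eye OD --out sectors.csv
retidiff cohort-stats --manifest manifest.csv --out report.csv
```

`retidiff segment` accepts a YAML `--config` overriding the run configuration
(`seed`, `median_window`, `denoise_window`, and any field of the `stage1:` /
`stage2:` diffusion configurations). The cohort manifest is a CSV with
columns `table,age,sex`, where `table` names a per-subject sector CSV.

## File formats

* **Volumes**: multi-page TIFF (one page per B-scan), NIfTI
  (`.nii`/`.nii.gz`), or raw float32 — each with a JSON sidecar carrying
  spacing, eye side, shape and subject metadata.
* **Surfaces**: TSV (one row per `(x, z)` column, one column per surface)
  plus a JSON sidecar with layer names.
* **Thickness**: per-layer CSV matrices + rendered PNG maps.
* **Sector tables / cohort reports**: plain CSV.

## Scope and limitations

* Validated on phantoms of the default size (64 x 128 x 16) and larger;
  volumes much smaller laterally starve the embedding of structural modes
  and degrade accuracy.
* Proprietary vendor formats (Heidelberg E2E, DICOM), image registration and
  motion correction are out of scope.
* Thickness is a per-column axial difference; no curvature correction.
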