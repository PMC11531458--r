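## Synthetic chest-CT phantoms with exact per-voxel tissue-fraction truth.
## The density model is HU = -1000 * (1 - f) for tissue fraction f in [0,1],
## the exact inverse of the voxel tissue-weight formula, so the generator
## provides an analytic oracle for calculated lung weight.

with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Describes a synthetic chest CT: grid shape and spacing, a lung made of two
#' ellipsoids inside a soft-tissue body, a base tissue fraction with an
#' optional linear gravitational aeration gradient, spherical consolidations,
#' contrast-agent blobs (HU > 200), and additive Gaussian HU noise.
#'
#' Sphere centers are given in 1-based voxel indices and radii in mm
#' (distances account for anisotropic spacing).
#'
#' @param shape three positive integers (grid size).
#' @param spacing voxel spacing in mm.
#' @param base_tissue_fraction tissue fraction in `[0, 1]` of plain lung.
#' @param gradient_axis axis (1-3) of the linear aeration gradient.
#' @param gradient_amplitude total tissue-fraction change across the grid
#'   along `gradient_axis` (ramp centered on `base_tissue_fraction`, result
#'   clipped to `[0, 1]`).
#' @param consolidations list of `list(center, radius_mm, tissue_fraction)`.
#' @param contrast_blobs list of `list(center, radius_mm, hu)` with `hu > 200`.
#' @param noise_sd HU standard deviation of additive Gaussian noise (>= 0).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                         base_tissue_fraction = 0.3, gradient_axis = 3L,
                         gradient_amplitude = 0, consolidations = list(),
                         contrast_blobs = list(), noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            length(spacing) == 3L, all(spacing > 0),
            base_tissue_fraction >= 0, base_tissue_fraction <= 1,
            gradient_axis %in% 1:3, noise_sd >= 0)
  for (cc in consolidations)
    if (cc$tissue_fraction < 0 || cc$tissue_fraction > 1)
      stop("consolidation tissue_fraction must lie in [0,1]", call. = FALSE)
  for (bb in contrast_blobs)
    if (bb$hu <= 200)
      stop("contrast blob HU must exceed 200", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 base_tissue_fraction = base_tissue_fraction,
                 gradient_axis = as.integer(gradient_axis),
                 gradient_amplitude = gradient_amplitude,
                 consolidations = consolidations,
                 contrast_blobs = contrast_blobs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# mm-coordinate grids for a spec (centers of voxels, 1-based index * spacing)
phantom_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# logical array: voxels inside the ellipsoid |(p - c)/semi|^2 <= 1 (mm units)
ellipsoid_mask <- function(shape, spacing, center_mm, semi_mm) {
  co <- phantom_coords(shape, spacing)
  dx2 <- ((co$x - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((co$y - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((co$z - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# sphere in mm around a voxel-index center
sphere_mask <- function(shape, spacing, center_idx, radius_mm) {
  center_mm <- (center_idx - 0.5) * spacing
  lo <- center_mm - radius_mm
  hi <- center_mm + radius_mm
  if (any(lo < 0) || any(hi > shape * spacing))
    stop("sphere at index (", paste(center_idx, collapse = ","),
         "), radius ", radius_mm, " mm extends outside the grid",
         call. = FALSE)
  ellipsoid_mask(shape, spacing, center_mm, rep(radius_mm, 3))
}

#' Generate a synthetic CT phantom with exact ground truth
#'
#' Within the lung mask, non-contrast voxels get
#' `HU = -1000 * (1 - tissue_fraction) + N(0, noise_sd)`; contrast voxels get
#' their specified HU exactly; outside the lungs the body is soft tissue
#' (+40 HU) surrounded by air (-1000 HU). The returned truth is computed from
#' the noise-free fractions over non-contrast lung voxels in double
#' precision.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [ct_volume()]), and `truth`
#'   (class `phantom_truth`: `tissue_fraction` array, `mask` a
#'   [lung_mask()], `contrast_mask` logical array, `true_tissue_mass` g,
#'   `true_gas_volume` ml).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; spacing <- spec$spacing
  vvol <- prod(spacing) / 1000  # ml

  ext <- shape * spacing
  body <- ellipsoid_mask(shape, spacing, ext / 2, ext * 0.48)
  lungs <- ellipsoid_mask(shape, spacing,
                          c(ext[1] * 0.30, ext[2] / 2, ext[3] / 2),
                          c(ext[1] * 0.17, ext[2] * 0.32, ext[3] * 0.38)) |
           ellipsoid_mask(shape, spacing,
                          c(ext[1] * 0.70, ext[2] / 2, ext[3] / 2),
                          c(ext[1] * 0.17, ext[2] * 0.32, ext[3] * 0.38))
  lungs <- lungs & body
  if (!any(lungs)) stop("degenerate phantom: empty lung mask", call. = FALSE)

  # noise-free tissue-fraction field
  frac <- array(spec$base_tissue_fraction, dim = shape)
  if (spec$gradient_amplitude != 0) {
    n_ax <- shape[spec$gradient_axis]
    ramp <- spec$gradient_amplitude * ((seq_len(n_ax) - 1) / (n_ax - 1) - 0.5)
    perm <- c(spec$gradient_axis, setdiff(1:3, spec$gradient_axis))
    ramp_arr <- aperm(array(ramp, dim = shape[perm]), order(perm))
    frac <- frac + ramp_arr
  }
  for (cc in spec$consolidations) {
    sp <- sphere_mask(shape, spacing, cc$center, cc$radius_mm)
    frac[sp] <- cc$tissue_fraction
  }
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1

  contrast <- array(FALSE, dim = shape)
  contrast_hu <- array(0, dim = shape)
  for (bb in spec$contrast_blobs) {
    sp <- sphere_mask(shape, spacing, bb$center, bb$radius_mm)
    contrast <- contrast | sp
    contrast_hu[sp] <- bb$hu
  }
  contrast <- contrast & lungs

  hu <- array(-1000, dim = shape)
  hu[body] <- 40
  lung_plain <- lungs & !contrast
  hu[lung_plain] <- -1000 * (1 - frac[lung_plain])
  if (spec$noise_sd > 0) {
    # one full-grid draw so the non-blob voxels are identical across specs
    # that differ only in contrast blobs (same seed)
    noise <- with_local_seed(spec$seed,
                             array(stats::rnorm(prod(shape), 0, spec$noise_sd),
                                   dim = shape))
    hu[lung_plain] <- hu[lung_plain] + noise[lung_plain]
  }
  hu[contrast] <- contrast_hu[contrast]

  vol <- ct_volume(hu, spacing)
  mask <- lung_mask(lungs, spacing)
  f_ok <- frac[lung_plain]
  truth <- structure(list(
    tissue_fraction = frac, mask = mask, contrast_mask = contrast,
    true_tissue_mass = sum(f_ok) * vvol,        # g (1 g/ml tissue)
    true_gas_volume = sum(1 - f_ok) * vvol),    # ml
    class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth: %d lung voxels (%d contrast), tissue %.2f g, gas %.2f ml\n",
              sum(x$mask$data), sum(x$contrast_mask),
              x$true_tissue_mass, x$true_gas_volume))
  invisible(x)
}

#' Cohort specification
#'
#' Statistical stand-in for an ARDS method-comparison cohort: anthropometrics
#' from truncated normals, true pulmonary edema from a lognormal, and a
#' CT-vs-thermodilution disagreement with a configured bias and SD. Defaults
#' emulate a 145-patient moderate-to-severe ARDS cohort (height 173 +/- 10 cm,
#' weight 90 +/- 26 kg, 33% female, thermodilution edema with median ~508 ml
#' and quartiles ~305-814 ml, TPTD-minus-CT disagreement bias -104 ml with
#' SD 1040/1.96 ml, CT-to-TPTD gap ~4.8 +/- 5.4 h).
#'
#' @param n number of patients (>= 1).
#' @param height_mean_cm,height_sd_cm height distribution, truncated > 120 cm.
#' @param weight_mean_kg,weight_sd_kg weight distribution, truncated > 30 kg.
#' @param female_frac probability of sex = female.
#' @param pe_meanlog,pe_sdlog lognormal parameters of true edema (ml).
#' @param disagreement_bias_ml mean of (TPTD edema - CT edema), ml.
#' @param disagreement_sd_ml SD of that difference, ml (>= 0).
#' @param gap_mean_h,gap_sd_h CT-to-TPTD time gap (h), normal truncated >= 0.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 145L, height_mean_cm = 173, height_sd_cm = 10,
                        weight_mean_kg = 90, weight_sd_kg = 26,
                        female_frac = 0.33,
                        pe_meanlog = log(508),
                        pe_sdlog = log(814 / 508) / stats::qnorm(0.75),
                        disagreement_bias_ml = -104,
                        disagreement_sd_ml = 1040 / 1.96,
                        gap_mean_h = 4.8, gap_sd_h = 5.4, seed = 1L) {
  stopifnot(n >= 1, height_sd_cm >= 0, weight_sd_kg >= 0,
            disagreement_sd_ml >= 0, gap_sd_h >= 0, pe_sdlog >= 0,
            female_frac >= 0, female_frac <= 1)
  structure(list(n = as.integer(n), height_mean_cm = height_mean_cm,
                 height_sd_cm = height_sd_cm, weight_mean_kg = weight_mean_kg,
                 weight_sd_kg = weight_sd_kg, female_frac = female_frac,
                 pe_meanlog = pe_meanlog, pe_sdlog = pe_sdlog,
                 disagreement_bias_ml = disagreement_bias_ml,
                 disagreement_sd_ml = disagreement_sd_ml,
                 gap_mean_h = gap_mean_h, gap_sd_h = gap_sd_h,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

#' Generate a synthetic method-comparison cohort
#'
#' Draws patient records and a paired (CT, thermodilution) edema observation
#' per patient. Both observations share the same true edema; the configured
#' disagreement is split symmetrically so that `pe_tptd - pe_ct` has mean
#' `disagreement_bias_ml` and SD `disagreement_sd_ml`. EVLWI is back-derived
#' from the TPTD-side edema and the Devine ideal body weight (clamped at 0,
#' `evlwi_clamped` flags affected rows); the returned `pe_tptd`/`pe_ct`
#' columns keep the unclamped values.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `patient_id`, `height_m`, `weight_kg`,
#'   `sex`, `evlwi_ml_per_kg`, `ct_time`, `tptd_time`, `pe_true`, `pe_ct`,
#'   `pe_tptd`, `evlwi_clamped`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_local_seed(spec$seed, {
    height_m <- rnorm_trunc(n, spec$height_mean_cm, spec$height_sd_cm,
                            lower = 120, upper = 249) / 100
    weight <- rnorm_trunc(n, spec$weight_mean_kg, spec$weight_sd_kg,
                          lower = 30)
    sex <- ifelse(stats::runif(n) < spec$female_frac, "female", "male")
    pe_true <- stats::rlnorm(n, spec$pe_meanlog, spec$pe_sdlog)
    half_sd <- spec$disagreement_sd_ml / sqrt(2)
    pe_tptd <- pe_true + spec$disagreement_bias_ml / 2 +
      stats::rnorm(n, 0, half_sd)
    pe_ct <- pe_true - spec$disagreement_bias_ml / 2 +
      stats::rnorm(n, 0, half_sd)
    gap_h <- rnorm_trunc(n, spec$gap_mean_h, spec$gap_sd_h, lower = 0)
    gap_sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
    ibw <- suppressWarnings(ideal_body_weight(height_m, sex))
    evlwi <- 7 + pe_tptd / ibw
    clamped <- evlwi < 0
    evlwi[clamped] <- 0
    ct_time <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") +
      (seq_len(n) - 1) * 86400
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      height_m = height_m, weight_kg = weight, sex = sex,
      evlwi_ml_per_kg = evlwi,
      ct_time = ct_time,
      tptd_time = ct_time + gap_sign * gap_h * 3600,
      pe_true = pe_true, pe_ct = pe_ct, pe_tptd = pe_tptd,
      evlwi_clamped = clamped,
      stringsAsFactors = FALSE)
  })
}
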