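#' CT volume container
#'
#' A `ct_volume` is a 3D scalar field of Hounsfield units (HU) together with
#' the voxel spacing (mm) taken from the image header. Voxel volume in ml is
#' `prod(spacing) / 1000`.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing numeric length-3 vector of voxel spacings in mm, all > 0.
#' @param clamp_range length-2 HU interval into which values are clamped
#'   (12-bit CT convention by default); use `NULL` to skip clamping.
#' @return An object of class `ct_volume` with elements `data`, `spacing`.
#' @export
ct_volume <- function(data, spacing, clamp_range = c(-1024, 3071)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("CT data must be a 3-dimensional array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm)", call. = FALSE)
  data <- clamp_hu(data, clamp_range)
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

clamp_hu <- function(x, clamp_range) {
  if (is.null(clamp_range)) return(x)
  stopifnot(length(clamp_range) == 2L, clamp_range[1] < clamp_range[2])
  x[x < clamp_range[1]] <- clamp_range[1]
  x[x > clamp_range[2]] <- clamp_range[2]
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", paste(dim(x$data), collapse = " x "), "voxels, spacing",
      paste(signif(x$spacing, 4), collapse = " x "),
      sprintf("mm (voxel %.4g ml)\n", voxel_volume_ml(x)))
  cat(sprintf("  HU range [%g, %g], mean %.1f\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param vol a `ct_volume` or `lung_mask`.
#' @return voxel volume in ml (spacing product in mm^3 / 1000).
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Binary lung mask container
#'
#' Delimits lung parenchyma on the same grid as the paired CT volume.
#' Values other than 0/1 (label maps from segmentation tools) are binarized
#' as `value > 0` with a warning.
#'
#' @param data 3D array; coerced to 0/1.
#' @param spacing voxel spacing in mm, as for [ct_volume()].
#' @return An object of class `lung_mask` with a logical `data` array.
#' @export
lung_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3-dimensional array", call. = FALSE)
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1)))
      warning("mask contains values outside {0,1}; binarizing as value > 0")
    data <- array(data > 0, dim = dim(data))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  n <- sum(x$data)
  cat("Lung mask:", paste(dim(x$data), collapse = " x "), "grid,",
      n, sprintf("voxels in mask (%.1f ml)\n", n * voxel_volume_ml(x)))
  invisible(x)
}

#' Read a CT volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param clamp_range HU clamp interval applied at ingest (default
#'   `c(-1024, 3071)`); `NULL` disables clamping.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, clamp_range = c(-1024, 3071)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop("expected 3D data, got ", length(d), " dimensions", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in header of ", path, call. = FALSE)
  ct_volume(array(as.numeric(img), dim = dim(img)), sp, clamp_range)
}

#' Write a CT volume (or mask) to NIfTI-1
#'
#' HU values are stored as 64-bit floats by default so that a write/read
#' round trip is exact; masks are stored as uint8.
#'
#' @param vol a `ct_volume` or `lung_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  if (inherits(vol, "lung_mask")) {
    arr <- array(as.integer(vol$data), dim = dim(vol$data))
    if (is.null(datatype)) datatype <- "uint8"
  } else if (inherits(vol, "ct_volume")) {
    arr <- vol$data
    if (is.null(datatype)) datatype <- "double"
  } else stop("vol must be a ct_volume or lung_mask", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary lung mask from NIfTI-1
#'
#' @inheritParams read_volume
#' @return a [lung_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, clamp_range = NULL)
  lung_mask(v$data, v$spacing)
}

#' Check that a volume and a mask live on the same grid
#'
#' A pure predicate: `TRUE` iff the array shapes match and the spacings agree
#' within `tol` mm per element. Quantification requires `TRUE`; callers are
#' expected to raise on `FALSE`.
#'
#' @param vol a `ct_volume`.
#' @param mask a `lung_mask` (or second `ct_volume`).
#' @param tol per-element spacing tolerance in mm.
#' @return logical scalar.
#' @export
check_grid_compatibility <- function(vol, mask, tol = 1e-3) {
  identical(dim(vol$data), dim(mask$data)) &&
    all(abs(vol$spacing - mask$spacing) <= tol)
}

#' Read a cohort table of patient records
#'
#' Expects a CSV with columns `patient_id`, `height_cm` (or `height_m`),
#' `weight_kg`, `sex` (`female`/`male`), `evlwi_ml_per_kg`, and optional
#' ISO-8601 `ct_time`, `tptd_time`. Heights are normalized to meters.
#'
#' @param path CSV path.
#' @return a data.frame with one validated row per patient: `patient_id`,
#'   `height_m`, `weight_kg`, `sex`, `evlwi_ml_per_kg`, `ct_time`,
#'   `tptd_time`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(raw)
}

validate_cohort <- function(raw) {
  if (!"height_m" %in% names(raw)) {
    if (!"height_cm" %in% names(raw))
      stop("cohort schema error: need a height_cm or height_m column",
           call. = FALSE)
    raw$height_m <- raw$height_cm / 100
  }
  needed <- c("patient_id", "weight_kg", "sex", "evlwi_ml_per_kg")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("cohort schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (tcol in c("ct_time", "tptd_time"))
    if (!tcol %in% names(raw)) raw[[tcol]] <- rep(NA_character_, nrow(raw))
  out <- data.frame(
    patient_id = as.character(raw$patient_id),
    height_m = as.numeric(raw$height_m),
    weight_kg = as.numeric(raw$weight_kg),
    sex = tolower(as.character(raw$sex)),
    evlwi_ml_per_kg = as.numeric(raw$evlwi_ml_per_kg),
    ct_time = parse_time(raw$ct_time, "ct_time"),
    tptd_time = parse_time(raw$tptd_time, "tptd_time"),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) return(out)
  check_row <- function(ok, field) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("cohort validation error: row %d, field %s out of range",
                   bad[1], field), call. = FALSE)
  }
  check_row(out$height_m > 1.0 & out$height_m < 2.5, "height")
  check_row(out$weight_kg > 0, "weight_kg")
  check_row(out$sex %in% c("female", "male"), "sex")
  check_row(is.na(out$evlwi_ml_per_kg) | out$evlwi_ml_per_kg >= 0,
            "evlwi_ml_per_kg")
  out
}

parse_time <- function(x, field) {
  if (all(is.na(x))) return(as.POSIXct(rep(NA_character_, length(x)), tz = "UTC"))
  out <- tryCatch(
    as.POSIXct(as.character(x), tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d")),
    error = function(e) stop("unparseable timestamp in column ", field,
                             call. = FALSE))
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable timestamp in column ", field, call. = FALSE)
  out
}

#' Write a cohort table to CSV
#' @param cohort data.frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (tcol in c("ct_time", "tptd_time"))
    if (tcol %in% names(out))
      out[[tcol]] <- format(out[[tcol]], "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
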