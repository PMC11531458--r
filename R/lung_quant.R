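#' Hounsfield-unit window
#'
#' A closed HU interval used to restrict voxel-density analysis. The edema
#' window used for contrast correction is `[-700, 200]` HU: voxels above
#' 200 HU are treated as contrast agent, voxels below -700 HU as
#' predominantly air.
#'
#' @param lower,upper window bounds in HU, `lower < upper`.
#' @return object of class `hu_window`.
#' @export
hu_window <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(lower < upper)) stop("window lower bound must be below upper bound",
                             call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "hu_window")
}

#' @rdname hu_window
#' @export
edema_window <- function() hu_window(-700, 200)

#' @export
print.hu_window <- function(x, ...) {
  cat(sprintf("HU window [%g, %g]\n", x$lower, x$upper)); invisible(x)
}

#' Tissue weight of voxels from their HU density
#'
#' `weight (g) = (1 - HU / -1000) * voxel volume (ml)`, i.e. the tissue
#' fraction is `1 + HU/1000` with air at -1000 HU weighing 0 and water at
#' 0 HU weighing 1 g/ml. No clipping is applied: HU > 0 yields more than
#' 1 g/ml, and HU below -1000 (prevented by clamping at ingest) would yield
#' negative weight.
#'
#' @param hu numeric vector of HU values.
#' @param voxel_volume voxel volume in ml (> 0).
#' @return weights in g, same length as `hu`.
#' @export
voxel_tissue_weight <- function(hu, voxel_volume) {
  stopifnot(voxel_volume > 0)
  (1 + hu / 1000) * voxel_volume
}

#' Voxel-density quantification of a masked lung
#'
#' Computes lung volume, mean HU, calculated lung weight (sum of per-voxel
#' tissue weights, algebraically equal to `(1 - meanHU/-1000) * volume`),
#' aerated volume (`sum(clamp(-HU/1000, 0, 1)) * voxel volume`) and tissue
#' volume (numerically equal to the weight, 1 g = 1 ml) over the masked
#' voxels. With a `window`, all sums are restricted to masked voxels whose
#' HU lies inside the window; the in-window (restricted) lung volume is
#' reported as `lung_volume` and the full-mask volume as
#' `lung_volume_unrestricted`.
#'
#' @param vol a [ct_volume()].
#' @param mask a [lung_mask()] on the same grid.
#' @param window optional [hu_window()]; `edema_window()` reproduces the
#'   contrast-corrected analysis.
#' @return object of class `lung_quant_result`: `lung_volume` (ml),
#'   `lung_volume_unrestricted` (ml), `mean_hu`, `calculated_lung_weight`
#'   (g), `aerated_volume` (ml), `tissue_volume` (ml), `n_voxels_total`,
#'   `n_voxels_in_window`, `n_excluded_above`, `n_excluded_below`,
#'   `voxel_volume_ml`, `window_used`.
#' @export
quantify_lung <- function(vol, mask, window = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "lung_mask"))
  if (!check_grid_compatibility(vol, mask))
    stop("volume and mask are not on the same grid", call. = FALSE)
  if (!is.null(window)) stopifnot(inherits(window, "hu_window"))
  hu_all <- vol$data[mask$data]
  n_total <- length(hu_all)
  if (n_total == 0L) stop("empty lung mask", call. = FALSE)
  vvol <- voxel_volume_ml(vol)

  if (is.null(window)) {
    hu <- hu_all
    n_above <- n_below <- 0L
  } else {
    inside <- hu_all >= window$lower & hu_all <= window$upper
    if (!any(inside))
      stop(sprintf("no masked voxel inside HU window [%g, %g]",
                   window$lower, window$upper), call. = FALSE)
    hu <- hu_all[inside]
    n_above <- sum(hu_all > window$upper)
    n_below <- sum(hu_all < window$lower)
  }
  n_used <- length(hu)
  weight <- sum(voxel_tissue_weight(hu, vvol))
  structure(list(
    lung_volume = n_used * vvol,
    lung_volume_unrestricted = n_total * vvol,
    mean_hu = mean(hu),
    calculated_lung_weight = weight,
    aerated_volume = sum(pmin(pmax(-hu / 1000, 0), 1)) * vvol,
    tissue_volume = weight,
    n_voxels_total = n_total,
    n_voxels_in_window = n_used,
    n_excluded_above = n_above,
    n_excluded_below = n_below,
    voxel_volume_ml = vvol,
    window_used = window), class = "lung_quant_result")
}

#' @export
print.lung_quant_result <- function(x, ...) {
  if (!is.null(x$window_used))
    cat(sprintf("Lung quantification (HU window [%g, %g]; %d voxels excluded above, %d below)\n",
                x$window_used$lower, x$window_used$upper,
                x$n_excluded_above, x$n_excluded_below))
  else cat("Lung quantification (all masked voxels)\n")
  cat(sprintf("  lung volume        %8.1f ml (%d voxels; full mask %.1f ml)\n",
              x$lung_volume, x$n_voxels_in_window, x$lung_volume_unrestricted))
  cat(sprintf("  mean HU            %8.1f\n", x$mean_hu))
  cat(sprintf("  calculated weight  %8.1f g\n", x$calculated_lung_weight))
  cat(sprintf("  aerated volume     %8.1f ml\n", x$aerated_volume))
  cat(sprintf("  tissue volume      %8.1f ml\n", x$tissue_volume))
  invisible(x)
}

#' CT-derived pulmonary edema (excessive lung weight)
#'
#' `edema (ml) = calculated lung weight - expected lung weight`, taking
#' 1 g of lung fluid as 1 ml of edema. The excessive-weight percentage is
#' `100 * (calculated - expected) / expected`. Negative values (calculated
#' below expected) are preserved and flagged.
#'
#' @param result a `lung_quant_result` (or a calculated weight in g).
#' @param expected_weight expected (height-predicted) lung weight, g (> 0).
#' @param method label: `"auto"`, `"autocorr"` or `"manual"`.
#' @return object of class `edema_estimate`: `method`, `edema_volume` (ml),
#'   `excessive_weight_pct`, `calculated_lung_weight`, `expected_lung_weight`,
#'   `negative` flag.
#' @export
edema_from_ct <- function(result, expected_weight,
                          method = c("auto", "autocorr", "manual")) {
  method <- match.arg(method)
  calc <- if (inherits(result, "lung_quant_result"))
    result$calculated_lung_weight else as.numeric(result)
  if (!is.finite(expected_weight) || expected_weight <= 0)
    stop("expected lung weight must be positive", call. = FALSE)
  edema <- calc - expected_weight
  structure(list(method = method,
                 edema_volume = edema,
                 excessive_weight_pct = 100 * edema / expected_weight,
                 calculated_lung_weight = calc,
                 expected_lung_weight = expected_weight,
                 negative = edema < 0), class = "edema_estimate")
}

#' @export
print.edema_estimate <- function(x, ...) {
  cat(sprintf("Pulmonary edema (%s): %.1f ml (excess weight %.1f%%)%s\n",
              x$method, x$edema_volume, x$excessive_weight_pct,
              if (isTRUE(x$negative)) " [calculated below expected]" else ""))
  invisible(x)
}
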