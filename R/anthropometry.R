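#' Expected (height-predicted) lung weight
#'
#' Cressoni linear model of healthy lung mass:
#' `expected weight (g) = -1806.1 + 1633.7 * height (m)`. The formula has a
#' positive root at height 1806.1/1633.7 ~ 1.1055 m; heights at or below it
#' (nonpositive predicted weight) are rejected, as are heights outside a
#' plausible adult range.
#'
#' @param height_m height in meters; vectorized.
#' @return expected lung weight in g.
#' @export
expected_lung_weight <- function(height_m) {
  root <- 1806.1 / 1633.7
  if (any(!is.finite(height_m)))
    stop("height must be finite", call. = FALSE)
  if (any(height_m <= 1.106))
    stop(sprintf(
      "height %.4g m is at or below the formula's positive-weight root (%.4f m); the linear model is only valid above it",
      min(height_m), root), call. = FALSE)
  if (any(height_m >= 2.5))
    stop("height must be below 2.5 m", call. = FALSE)
  -1806.1 + 1633.7 * height_m
}

#' Ideal body weight
#'
#' Devine formula (default): male `50 + 0.91 * (height_cm - 152.4)` kg,
#' female `45.5 + 0.91 * (height_cm - 152.4)` kg. The ARDSNet predicted body
#' weight uses the same intercepts with 2.3 kg per inch over 60 in (0.9055
#' kg/cm), differing from Devine only in unit rounding. Results below 30 kg
#' (very short heights) are floored at 30 kg with a warning.
#'
#' @param height_m height in meters; vectorized.
#' @param sex `"female"` or `"male"` (recycled).
#' @param formula `"devine"` (default) or `"ardsnet"`.
#' @return ideal body weight in kg.
#' @export
ideal_body_weight <- function(height_m, sex, formula = c("devine", "ardsnet")) {
  formula <- match.arg(formula)
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  base <- ifelse(sex == "male", 50, 45.5)
  ibw <- switch(formula,
    devine  = base + 0.91 * (height_m * 100 - 152.4),
    ardsnet = base + 2.3 * (height_m * 100 / 2.54 - 60))
  if (any(ibw < 30)) {
    warning("ideal body weight below 30 kg floored at 30 kg")
    ibw <- pmax(ibw, 30)
  }
  ibw
}

#' Thermodilution-derived pulmonary edema
#'
#' All extravascular lung water above the physiological amount is counted as
#' edema: `physiological lung water (ml) = threshold (ml/kg) * IBW (kg)` and
#' `PE_TPTD (ml) = (EVLWI - threshold) * IBW`. The physiological threshold
#' defaults to 7 ml/kg; values of EVLWI below it give negative edema, which
#' is preserved and flagged `sub_physiological`.
#'
#' Accepts either a cohort data.frame (columns `evlwi_ml_per_kg`, `height_m`,
#' `sex`) or parallel vectors.
#'
#' @param evlwi EVLWI in ml/kg, or a cohort data.frame.
#' @param height_m,sex patient height (m) and sex, ignored when `evlwi` is a
#'   data.frame.
#' @param threshold physiological lung water threshold, ml/kg.
#' @param ibw_formula passed to [ideal_body_weight()].
#' @return data.frame with columns `evlwi`, `ibw`, `physiological_lung_water`
#'   (ml), `pe_tptd` (ml), `sub_physiological`.
#' @export
edema_from_tptd <- function(evlwi, height_m = NULL, sex = NULL, threshold = 7,
                            ibw_formula = "devine") {
  if (is.data.frame(evlwi)) {
    df <- evlwi
    needed <- c("evlwi_ml_per_kg", "height_m", "sex")
    missing <- setdiff(needed, names(df))
    if (length(missing))
      stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    evlwi <- df$evlwi_ml_per_kg; height_m <- df$height_m; sex <- df$sex
  }
  if (is.null(evlwi) || any(is.na(evlwi)))
    stop("missing EVLWI value", call. = FALSE)
  if (any(evlwi < 0)) stop("EVLWI must be nonnegative", call. = FALSE)
  ibw <- ideal_body_weight(height_m, sex, ibw_formula)
  plw <- threshold * ibw
  pe <- (evlwi - threshold) * ibw
  data.frame(evlwi = evlwi, ibw = ibw, physiological_lung_water = plw,
             pe_tptd = pe, sub_physiological = pe < 0)
}

#' Pair CT and thermodilution measurements within a synchronization window
#'
#' Keeps one measurement pair per patient: when a patient has several CT
#' scans only the first (earliest `ct_time`) is considered, and the pair is
#' retained only when the absolute CT-to-TPTD gap is at most `max_gap_hours`
#' (default 24 h). Idempotent and independent of input row order.
#'
#' @param records data.frame with `patient_id`, `ct_time`, `tptd_time`
#'   (POSIXct or ISO-8601 strings) plus any payload columns.
#' @param max_gap_hours synchronization window in hours.
#' @return the retained rows, one per patient, ordered by `patient_id`, with
#'   an added `gap_hours` column.
#' @export
pair_measurements <- function(records, max_gap_hours = 24) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "ct_time", "tptd_time") %in% names(records)))
  rec <- records
  for (tcol in c("ct_time", "tptd_time"))
    if (!inherits(rec[[tcol]], "POSIXct"))
      rec[[tcol]] <- parse_time(rec[[tcol]], tcol)
  if (any(is.na(rec$ct_time)) || any(is.na(rec$tptd_time)))
    stop("unparseable or missing timestamps", call. = FALSE)
  rec <- rec[order(rec$patient_id, rec$ct_time), , drop = FALSE]
  rec <- rec[!duplicated(rec$patient_id), , drop = FALSE]
  rec$gap_hours <- abs(as.numeric(difftime(rec$ct_time, rec$tptd_time,
                                           units = "hours")))
  rec <- rec[rec$gap_hours <= max_gap_hours, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
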