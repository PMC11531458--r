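#' Bland-Altman agreement analysis
#'
#' Differences are taken as `x - y` (the caller chooses the orientation; for
#' edema comparisons the package convention is thermodilution minus CT).
#' Bias is the mean difference, the 95% limits of agreement are
#' `bias +/- loa_multiplier * sd` with the sample SD (n - 1 denominator) and
#' multiplier 1.96 by default. Normal-theory confidence intervals use
#' `SE(bias) = sd/sqrt(n)` and
#' `SE(LoA) = sd * sqrt(1/n + multiplier^2 / (2(n-1)))` with t quantiles.
#'
#' @param x,y paired measurements (same units), length >= 3.
#' @param loa_multiplier multiplier for the limits of agreement.
#' @param conf_level confidence level for the intervals.
#' @return object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`.
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (any(!is.finite(d))) stop("measurements must be pairwise finite",
                               call. = FALSE)
  n <- length(d)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 pairs",
                  call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  if (s == 0) warning("zero variance of differences: limits of agreement collapse to the bias")
  half <- loa_multiplier * s
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + loa_multiplier^2 / (2 * (n - 1)))
  structure(list(
    n = n, bias = bias, sd_diff = s,
    loa_lower = bias - half, loa_upper = bias + half,
    loa_multiplier = loa_multiplier, conf_level = conf_level,
    ci_bias = bias + c(-1, 1) * tq * se_bias,
    ci_loa_lower = bias - half + c(-1, 1) * tq * se_loa,
    ci_loa_upper = bias + half + c(-1, 1) * tq * se_loa),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d, differences x - y)\n", x$n))
  cat(sprintf("  bias  %9.1f  [%.1f, %.1f] %d%% CI\n", x$bias,
              x$ci_bias[1], x$ci_bias[2], round(100 * x$conf_level)))
  cat(sprintf("  LoA   %9.1f  [%.1f, %.1f]\n", x$loa_lower,
              x$ci_loa_lower[1], x$ci_loa_lower[2]))
  cat(sprintf("        %9.1f  [%.1f, %.1f]   (bias +/- %.2f x SD, SD = %.1f)\n",
              x$loa_upper, x$ci_loa_upper[1], x$ci_loa_upper[2],
              x$loa_multiplier, x$sd_diff))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation; via [stats::cor.test()]).
#'
#' @param x,y paired samples, length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Segmentation overlap indices (Jaccard and Dice)
#'
#' `jaccard = |A intersect B| / |A union B|`;
#' `dice = 2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined as
#' perfectly overlapping (both indices 1) with a warning.
#'
#' @param a,b two [lung_mask()]s on the same grid.
#' @return object of class `overlap_result`: `jaccard`, `dice`,
#'   `intersection_voxels`, `union_voxels`.
#' @export
overlap_indices <- function(a, b) {
  stopifnot(inherits(a, "lung_mask"), inherits(b, "lung_mask"))
  if (!check_grid_compatibility(a, b))
    stop("masks are not on the same grid", call. = FALSE)
  inter <- sum(a$data & b$data)
  uni <- sum(a$data | b$data)
  if (uni == 0L) {
    warning("both masks are empty; overlap defined as 1")
    j <- 1; dce <- 1
  } else {
    j <- inter / uni
    dce <- 2 * inter / (sum(a$data) + sum(b$data))
    stopifnot(abs(dce - 2 * j / (1 + j)) < 1e-12)  # identity sanity check
  }
  structure(list(jaccard = j, dice = dce,
                 intersection_voxels = inter, union_voxels = uni),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Mask overlap: Jaccard %.3f, Dice %.3f (%d / %d voxels)\n",
              x$jaccard, x$dice, x$intersection_voxels, x$union_voxels))
  invisible(x)
}

#' Summarize segmentation-quality grades
#'
#' Tallies three-point semiquantitative grades (1 good, 2 moderate, 3 poor)
#' into counts, exact fractions and display percentages (rounded to
#' integers).
#'
#' @param grades vector of grades in `{1, 2, 3}`.
#' @param n_expected optional expected total; a mismatch is an error.
#' @return object of class `grade_summary`: `counts`, `fractions`,
#'   `pct_display`, `n_total`.
#' @export
summarize_grades <- function(grades, n_expected = NULL) {
  if (length(grades) == 0) stop("no grades supplied", call. = FALSE)
  if (!all(grades %in% 1:3))
    stop("grades must be 1, 2 or 3", call. = FALSE)
  if (!is.null(n_expected) && length(grades) != n_expected)
    stop(sprintf("expected %d grades, got %d", n_expected, length(grades)),
         call. = FALSE)
  counts <- tabulate(grades, nbins = 3L)
  names(counts) <- c("good", "moderate", "poor")
  frac <- counts / length(grades)
  structure(list(counts = counts, fractions = frac,
                 pct_display = round(100 * frac), n_total = length(grades)),
            class = "grade_summary")
}

#' @export
print.grade_summary <- function(x, ...) {
  cat(sprintf("Segmentation grading (n = %d): 1 good %d (%d%%), 2 moderate %d (%d%%), 3 poor %d (%d%%)\n",
              x$n_total, x$counts[1], x$pct_display[1], x$counts[2],
              x$pct_display[2], x$counts[3], x$pct_display[3]))
  invisible(x)
}

#' Paired location test
#'
#' Two-sided paired Student t test or Wilcoxon signed-rank test. A t test on
#' zero-variance differences is degenerate and raises an error.
#'
#' @param x,y paired samples, length >= 3.
#' @param method `"t"` or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `method`, `n`.
#' @export
paired_location_test <- function(x, y, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  if (any(!is.finite(d))) stop("samples must be pairwise finite", call. = FALSE)
  if (method == "t") {
    if (stats::sd(d) == 0)
      stop("degenerate input: zero variance of paired differences under the t test",
           call. = FALSE)
    ht <- stats::t.test(x, y, paired = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, n = length(x))
}

#' Monte-Carlo power of a Bland-Altman agreement study
#'
#' Estimates the probability that an agreement study of `n` pairs, whose
#' differences are N(`true_bias`, `true_sd`), concludes acceptable
#' agreement: both estimated limits of agreement, including their
#' `conf_level` confidence bounds, fall inside
#' `[-max_allowed_difference, +max_allowed_difference]`. The confidence
#' bounds use the same normal-theory standard errors as [bland_altman()].
#'
#' @param n pairs per study (>= 3).
#' @param true_bias,true_sd difference distribution (ml); `true_sd > 0`.
#' @param max_allowed_difference clinically acceptable maximum difference.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed RNG seed (local to the call).
#' @param loa_multiplier,conf_level as in [bland_altman()].
#' @return power estimate in `[0, 1]`, with attributes `mc_se` (Monte-Carlo
#'   standard error) and `reps`.
#' @export
bland_altman_power <- function(n, true_bias, true_sd, max_allowed_difference,
                               reps = 1000L, seed = 1L,
                               loa_multiplier = 1.96, conf_level = 0.95) {
  stopifnot(n >= 3, true_sd > 0, reps >= 100)
  if (max_allowed_difference <= abs(true_bias) + loa_multiplier * true_sd)
    warning("maximum allowed difference lies inside the true limits of agreement; power will be near 0")
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_fac <- sqrt(1 / n + loa_multiplier^2 / (2 * (n - 1)))
  with_local_seed(seed, {
    d <- matrix(stats::rnorm(n * reps, true_bias, true_sd), nrow = n)
    m <- colMeans(d)
    s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
    upper_bound <- m + loa_multiplier * s + tq * s * se_fac
    lower_bound <- m - loa_multiplier * s - tq * s * se_fac
    ok <- upper_bound < max_allowed_difference &
      lower_bound > -max_allowed_difference
    p <- mean(ok)
    structure(p, mc_se = sqrt(p * (1 - p) / reps), reps = reps)
  })
}
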