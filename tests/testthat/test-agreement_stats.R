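test_that("Bland-Altman bias and limits of agreement are the symmetric 1.96-SD construction", {
  # hand-computed: d = {-1, 0, 1} has mean 0 and sample SD exactly 1
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  # midpoint of the limits is the bias, exactly
  expect_equal((ba$loa_lower + ba$loa_upper) / 2, ba$bias)
  # CI construction
  expect_equal(ba$ci_bias, 0 + c(-1, 1) * qt(0.975, 2) / sqrt(3))

  # identical methods collapse the limits onto a zero bias
  expect_warning(ba0 <- bland_altman(c(3, 4, 5, 6), c(3, 4, 5, 6)),
                 "collapse")
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  expect_error(bland_altman(1:2, 2:3), "at least 3")
  expect_error(bland_altman(c(1, NA, 3), c(1, 2, 3)), "finite")

  # recovers the generating (bias, SD) on large simulated cohorts
  set.seed(21)
  d <- rnorm(1e5, -104, 1040 / 1.96)
  ba_big <- bland_altman(d, rep(0, 1e5))
  expect_equal(ba_big$bias, -104, tolerance = 6 * (1040 / 1.96) / sqrt(1e5) / 104)
  expect_equal(ba_big$loa_lower, -1144, tolerance = 0.02)
  expect_equal(ba_big$loa_upper, 936, tolerance = 0.02)

  # configurable multiplier
  ba_t <- bland_altman(c(0, 1, 2), c(1, 1, 1), loa_multiplier = 2.5)
  expect_equal(ba_t$loa_upper, 2.5)
})

test_that("Spearman correlation matches the brute-force rank oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3)$rho, -1)
  # sum of squared rank differences is 4: 1 - 6*4/120 = 0.8
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_equal(brute_spearman(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")

  set.seed(33)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.01)
    y <- sample(1:5, n, replace = TRUE)  # ties on purpose
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y)$rho, brute_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Jaccard and Dice overlap indices obey their identities", {
  dims <- c(6, 6, 6)
  a <- lung_mask(array(rep(c(TRUE, FALSE), length.out = 216), dim = dims),
                 c(1, 1, 1))
  expect_equal(overlap_indices(a, a)$jaccard, 1)
  expect_equal(overlap_indices(a, a)$dice, 1)
  b <- lung_mask(array(!a$data, dim = dims), c(1, 1, 1))
  expect_equal(overlap_indices(a, b)$jaccard, 0)
  expect_equal(overlap_indices(a, b)$dice, 0)

  # counting example: |A|=|B|=100, overlap 80 -> J = 80/120, D = 160/200
  m1 <- array(FALSE, dim = c(10, 10, 10)); m1[1:100] <- TRUE
  m2 <- array(FALSE, dim = c(10, 10, 10)); m2[21:120] <- TRUE
  ov <- overlap_indices(lung_mask(m1, c(1, 1, 1)), lung_mask(m2, c(1, 1, 1)))
  expect_equal(ov$intersection_voxels, 80L)
  expect_equal(ov$union_voxels, 120L)
  expect_equal(ov$jaccard, 2 / 3)
  expect_equal(ov$dice, 0.8)
  expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard))

  empty <- lung_mask(array(FALSE, dim = dims), c(1, 1, 1))
  expect_warning(ov0 <- overlap_indices(empty, empty), "empty")
  expect_equal(ov0$jaccard, 1)
  expect_error(overlap_indices(a, lung_mask(array(TRUE, dim = c(5, 5, 5)),
                                            c(1, 1, 1))), "grid")
})

test_that("grade summaries tally counts and rounded percentages", {
  g <- c(rep(1, 97), rep(2, 29), rep(3, 19))
  s <- summarize_grades(g, n_expected = 145)
  expect_equal(unname(s$counts), c(97, 29, 19))
  expect_equal(unname(s$pct_display), c(67, 20, 13))
  expect_equal(sum(s$counts), s$n_total)
  expect_equal(sum(s$fractions), 1)

  s1 <- summarize_grades(rep(1, 10))
  expect_equal(unname(s1$pct_display), c(100, 0, 0))
  su <- summarize_grades(c(1, 2, 3))
  expect_equal(unname(su$pct_display), c(33, 33, 33))
  expect_equal(unname(su$fractions), rep(1 / 3, 3))

  expect_error(summarize_grades(c(1, 4)), "1, 2 or 3")
  expect_error(summarize_grades(integer(0)), "no grades")
  expect_error(summarize_grades(c(1, 2), n_expected = 3), "expected 3")
})

test_that("paired location tests behave on degenerate and shifted data", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(paired_location_test(x, x, "t"), "degenerate")
  w <- paired_location_test(x, x, "wilcoxon")
  expect_true(is.na(w$p_value) || w$p_value > 0.99)

  # an exactly constant nonzero shift is degenerate under t (zero variance)
  expect_error(paired_location_test(x, x + 5, "t"), "degenerate")
  # with any jitter the shift is detected decisively
  set.seed(7)
  xx <- rep(x, 4)
  yy <- xx + 5 + rnorm(20, 0, 0.01)
  expect_lt(paired_location_test(yy, xx, "t")$p_value, 1e-6)

  # empirical power agrees with the closed-form noncentral-t oracle
  n <- 145; shift <- 100; s <- 500; reps <- 2000
  oracle <- power.t.test(n = n, delta = shift, sd = s,
                         type = "one.sample")$power
  set.seed(55)
  hits <- 0
  for (r in seq_len(reps)) {
    d <- rnorm(n, shift, s)
    if (paired_location_test(d, rep(0, n), "t")$p_value < 0.05)
      hits <- hits + 1
  }
  emp <- hits / reps
  expect_lt(abs(emp - oracle), 4 * sqrt(oracle * (1 - oracle) / reps))
})

test_that("agreement-study power simulation responds to the acceptability limit", {
  expect_equal(as.numeric(bland_altman_power(20, 0, 100, 1e9, reps = 200,
                                             seed = 2)), 1)
  expect_warning(
    p0 <- bland_altman_power(20, 500, 100, 400, reps = 200, seed = 2),
    "near 0")
  expect_lt(as.numeric(p0), 0.01)
  # deterministic given seed
  p1 <- bland_altman_power(145, 30, 290, 700, reps = 500, seed = 9)
  p2 <- bland_altman_power(145, 30, 290, 700, reps = 500, seed = 9)
  expect_identical(as.numeric(p1), as.numeric(p2))
  # monotone in the allowed difference
  p_tight <- bland_altman_power(145, 30, 290, 620, reps = 500, seed = 9)
  expect_gt(as.numeric(p1), as.numeric(p_tight))
})
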