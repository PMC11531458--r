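# Independent oracles and small fixture builders used across test files.

# average ranks computed by counting, independent of base::rank
average_rank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# brute-force Spearman: rank by counting, then the product-moment formula
# written out from sums
brute_spearman <- function(x, y) {
  rx <- average_rank(x); ry <- average_rank(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt(n * sum(rx^2) - sx^2) * sqrt(n * sum(ry^2) - sy^2)
  num / den
}

# uniform-HU cube volume+mask pair: n_mask voxels of the given HU inside an
# air background, unit spacing unless given
uniform_fixture <- function(hu, n_mask = 1000L, dims = c(10L, 10L, 10L),
                            spacing = c(1, 1, 1)) {
  stopifnot(n_mask <= prod(dims))
  arr <- array(-1000, dim = dims)
  m <- array(FALSE, dim = dims)
  m[seq_len(n_mask)] <- TRUE
  arr[m] <- hu
  list(vol = ct_volume(arr, spacing), mask = lung_mask(m, spacing))
}

# random lung_mask on a small grid
random_mask <- function(dims = c(6L, 6L, 6L), p = 0.5, spacing = c(1, 1, 1)) {
  lung_mask(array(stats::runif(prod(dims)) < p, dim = dims), spacing)
}
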