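# Independent oracle implementations used to check the package's fast paths.
# Each recomputes its quantity directly from the definition, sharing no code
# with the implementation under test.

# Exhaustive O(n^2) one-step fit: recompute the SSE at every step position
# by direct summation over the residuals.
oracle_fit_step <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  sse <- vapply(1:(n - 1), function(k) {
    lo <- x[1:k]
    hi <- x[(k + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(sse)
  list(k = k, sse = sse[k],
       threshold = (mean(x[1:k]) + mean(x[(k + 1):n])) / 2)
}

# Scalar evaluation of the sparsity statistics for one quadrant, straight
# from the printed formulas.
oracle_quadrant_stat <- function(a00, a01, a10, a11, i, j) {
  total <- a00 + a01 + a10 + a11
  a <- matrix(c(a00, a01, a10, a11), 2, byrow = TRUE)[i + 1, j + 1]
  n_a <- if (i == 0) a00 + a01 else a10 + a11
  n_b <- if (j == 0) a00 + a10 else a01 + a11
  nhat <- (n_a / total) * (n_b / total) * total
  list(
    expected = nhat,
    s = if (nhat > 0) (nhat - a) / sqrt(nhat) else 0,
    p = if (n_a > 0 && n_b > 0) 0.5 * (a / n_a + a / n_b) else NA_real_
  )
}

# Naive sort-then-weight gene scores.
oracle_gene_scores <- function(M) {
  n <- nrow(M)
  vapply(seq_len(n), function(i) {
    sorted <- sort(M[i, ])
    sum((seq_len(n) - 1) * sorted / 2) / n
  }, numeric(1))
}

# Small compendium used across module tests: a 12-probe planted equivalence
# cluster, 4 subset probes, 150 noise probes, 300 samples.
small_sim <- function(rng_seed = 101) {
  generate_compendium(synthetic_config(
    n_samples = 300, n_universal = 12, n_subset = 4, n_noise = 150,
    rng_seed = rng_seed
  ))
}

# Random quadrant counts with a nonzero total.
random_counts <- function(max_cell = 60) {
  repeat {
    a <- sample.int(max_cell + 1, 4, replace = TRUE) - 1L
    if (sum(a) > 0) return(new_quadrant_counts(a[1], a[2], a[3], a[4]))
  }
}
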