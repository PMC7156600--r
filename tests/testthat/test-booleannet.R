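test_that("quadrant counts drop intermediate and missing samples", {
  expect_equal(
    unclass(quadrant_counts(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)))[1:5],
    list(a00 = 2L, a01 = 0L, a10 = 0L, a11 = 2L, total = 4L)
  )
  c2 <- quadrant_counts(c(0L, 2L, 1L), c(1L, 1L, 0L))
  expect_equal(c(c2$a00, c2$a01, c2$a10, c2$a11), c(0, 1, 1, 0))
  c3 <- quadrant_counts(c(0L, NA, 1L), c(1L, 1L, NA))
  expect_equal(c3$total, 1)
  expect_error(quadrant_counts(c(0L, 1L), c(0L)), "length")
})

test_that("sparsity statistics match hand evaluation and the independence null", {
  st <- sparsity_stat(new_quadrant_counts(50, 0, 0, 50), 0, 1)
  expect_equal(st$expected, 25)
  expect_equal(st$s, 5)
  expect_equal(st$p, 0)
  st10 <- sparsity_stat(new_quadrant_counts(50, 0, 0, 50), 1, 0)
  expect_equal(st10$s, 5)

  ind <- quadrant_stats(new_quadrant_counts(25, 25, 25, 25))
  expect_equal(ind$expected, rep(25, 4))
  expect_equal(ind$s, rep(0, 4))
  expect_equal(ind$p, rep(0.5, 4))

  expect_error(quadrant_stats(new_quadrant_counts(0, 0, 0, 0)),
               "no informative samples")
})

test_that("statistics equal an independent evaluation of the printed formulas", {
  set.seed(99)
  got <- list(expected = c(), s = c(), p = c())
  want <- list(expected = c(), s = c(), p = c())
  for (rep in 1:1000) {
    counts <- random_counts()
    stats <- quadrant_stats(counts)
    o <- lapply(1:4, function(q) {
      oracle_quadrant_stat(counts$a00, counts$a01, counts$a10,
                           counts$a11, stats$i[q], stats$j[q])
    })
    got$expected <- c(got$expected, stats$expected)
    got$s <- c(got$s, stats$s)
    got$p <- c(got$p, stats$p)
    want$expected <- c(want$expected, vapply(o, `[[`, 1, "expected"))
    want$s <- c(want$s, vapply(o, `[[`, 1, "s"))
    want$p <- c(want$p, vapply(o, `[[`, 1, "p"))
  }
  # tolerance covers association-order rounding between the two evaluations
  expect_equal(got$expected, want$expected, tolerance = 1e-12)
  expect_equal(got$s, want$s, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("each of the six relations arises from its sparse-quadrant pattern", {
  rel <- function(...) classify_pair(new_quadrant_counts(...))$relation
  expect_identical(rel(50, 0, 0, 50), "EQUIVALENT")
  expect_identical(rel(0, 50, 50, 0), "OPPOSITE")
  expect_identical(rel(0, 40, 40, 20), "LOW_HIGH")   # sparse (0,0): A low => B high
  expect_identical(rel(40, 0, 20, 40), "LOW_LOW")    # sparse (0,1): A low => B low
  expect_identical(rel(40, 20, 0, 40), "HIGH_HIGH")  # sparse (1,0): A high => B high
  expect_identical(rel(40, 30, 40, 0), "HIGH_LOW")   # sparse (1,1): A high => B low
  expect_identical(rel(25, 25, 25, 25), "NONE")
})

test_that("classification respects the small-sample guard and precedence rules", {
  # same sparse geometry, below a raised informative-sample floor
  small <- classify_pair(new_quadrant_counts(50, 0, 0, 50), min_total = 150)
  expect_identical(small$relation, "NONE")
  expect_identical(small$flag, "low_total")
  # all-intermediate pair
  expect_identical(
    classify_pair(quadrant_counts(c(2L, 2L), c(2L, 2L)))$relation, "NONE"
  )
  # diagonal sparse pairs always classify symmetric, never asymmetric
  set.seed(5)
  for (rep in 1:200) {
    counts <- random_counts()
    res <- classify_pair(counts, min_total = 1)
    stats <- res$stats
    if (is.null(stats)) next
    sparse <- !stats$undefined & !is.na(stats$p) & stats$s > 3 & stats$p < 0.1
    if (sum(sparse) == 2 && setequal(stats$quadrant[sparse], c("01", "10"))) {
      expect_identical(res$relation, "EQUIVALENT")
    }
    if (sum(sparse) == 2 && setequal(stats$quadrant[sparse], c("00", "11"))) {
      expect_identical(res$relation, "OPPOSITE")
    }
    if (sum(sparse) >= 3) {
      expect_identical(res$relation, "NONE")
      expect_identical(res$flag, "ambiguous")
    }
  }
})

test_that("classification is mirror-symmetric under swapping the two probes", {
  mirror <- c(EQUIVALENT = "EQUIVALENT", OPPOSITE = "OPPOSITE",
              LOW_LOW = "HIGH_HIGH", HIGH_HIGH = "LOW_LOW",
              LOW_HIGH = "LOW_HIGH", HIGH_LOW = "HIGH_LOW",
              NONE = "NONE")
  set.seed(17)
  for (rep in 1:300) {
    counts <- random_counts()
    swapped <- new_quadrant_counts(counts$a00, counts$a10,
                                   counts$a01, counts$a11)
    r1 <- classify_pair(counts, min_total = 1)$relation
    r2 <- classify_pair(swapped, min_total = 1)$relation
    expect_identical(r2, unname(mirror[r1]))
  }
})

test_that("scan_equivalents recovers a planted cluster and handles edge probes", {
  sim <- small_sim()
  calls <- booleanize(sim$expr)
  uni <- sim$truth$probe_id[sim$truth$label == "universal"]

  found <- scan_equivalents(calls, "UNI001_at")[["UNI001_at"]]
  expect_setequal(found, setdiff(uni, "UNI001_at"))

  # two probes with identical values report each other
  dup <- rbind(sim$expr, DUP001_at = sim$expr["UNI001_at", ])
  dup_calls <- booleanize(dup)
  res <- scan_equivalents(dup_calls, c("UNI001_at", "DUP001_at"))
  expect_true("DUP001_at" %in% res[["UNI001_at"]])
  expect_true("UNI001_at" %in% res[["DUP001_at"]])

  # a constant probe has no informative calls, hence no equivalents
  const <- rbind(sim$expr, CST001_at = rep(5, ncol(sim$expr)))
  expect_length(scan_equivalents(booleanize(const), "CST001_at")[[1]], 0)

  expect_error(scan_equivalents(calls, "NOPE_at"), "unknown query")
})

test_that("probe_implication ties the modules together", {
  sim <- small_sim()
  imp <- probe_implication(sim$expr, "SUB001_at", "UNI001_at")
  expect_identical(imp$relation, "HIGH_HIGH") # subset high => universal high
  imp2 <- probe_implication(sim$expr, "UNI001_at", "SUB001_at")
  expect_identical(imp2$relation, "LOW_LOW")
  td <- tidy(imp)
  expect_identical(td$relation, "HIGH_HIGH")
  expect_true(all(c("s_00", "p_00", "s_11", "p_11") %in% names(td)))
  expect_error(probe_implication(sim$expr, "UNI001_at", "NOPE"), "unknown")
})
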