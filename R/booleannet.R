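#' Quadrant counts for a pair of Boolean call vectors
#'
#' Cross-tabulates two ternary call vectors over the samples where both
#' calls are LOW or HIGH; INTERMEDIATE and missing samples are dropped.
#' The first index is the call of probe A, the second of probe B
#' (0 = LOW, 1 = HIGH), so `a01` counts samples with A low and B high.
#'
#' @param calls_a,calls_b Integer call vectors over the same ordered samples
#'   (coding as produced by [booleanize()]).
#' @return An object of class `quadrant_counts`: list with `a00`, `a01`,
#'   `a10`, `a11` and `total`.
#' @examples
#' quadrant_counts(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
#' @export
quadrant_counts <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length (", length(calls_a), " vs ",
         length(calls_b), ")")
  }
  keep <- !is.na(calls_a) & !is.na(calls_b) &
    calls_a != CALL_INTERMEDIATE & calls_b != CALL_INTERMEDIATE
  a <- calls_a[keep]
  b <- calls_b[keep]
  new_quadrant_counts(
    a00 = sum(a == 0L & b == 0L), a01 = sum(a == 0L & b == 1L),
    a10 = sum(a == 1L & b == 0L), a11 = sum(a == 1L & b == 1L)
  )
}

#' Construct quadrant counts directly
#'
#' @param a00,a01,a10,a11 Non-negative integer counts; first index = call of
#'   probe A, second = call of probe B.
#' @return A `quadrant_counts` object.
#' @export
new_quadrant_counts <- function(a00, a01, a10, a11) {
  counts <- c(a00 = a00, a01 = a01, a10 = a10, a11 = a11)
  if (any(counts < 0)) stop("quadrant counts must be non-negative")
  structure(list(a00 = a00, a01 = a01, a10 = a10, a11 = a11,
                 total = a00 + a01 + a10 + a11),
            class = "quadrant_counts")
}

#' @export
print.quadrant_counts <- function(x, ...) {
  m <- matrix(c(x$a00, x$a01, x$a10, x$a11), 2, byrow = TRUE,
              dimnames = list(A = c("low", "high"), B = c("low", "high")))
  print(m)
  invisible(x)
}

#' BooleanNet sparsity statistics for every quadrant
#'
#' For quadrant `(i, j)` with observed count `n = a_ij`, the expected count
#' under independence is `nhat = (nA_i / total) * (nB_j / total) * total`
#' where `nA_i`, `nB_j` are the marginal counts of A in state `i` and B in
#' state `j`. The sparsity statistic is `S = (nhat - n) / sqrt(nhat)` and the
#' error rate is the mean of the two conditional probabilities of landing in
#' the quadrant, `p = (a_ij / nA_i + a_ij / nB_j) / 2`. Quadrants with
#' `nhat = 0` report `S = 0` with `undefined = TRUE` and are never considered
#' sparse.
#'
#' @param counts A `quadrant_counts` object.
#' @return A tibble with one row per quadrant: `quadrant`, `i`, `j`, `n`,
#'   `expected`, `s`, `p`, `undefined`.
#' @examples
#' quadrant_stats(new_quadrant_counts(50, 0, 0, 50))
#' @export
quadrant_stats <- function(counts) {
  stopifnot(inherits(counts, "quadrant_counts"))
  if (counts$total == 0) {
    stop("no informative samples: all calls intermediate or missing")
  }
  a <- c(counts$a00, counts$a01, counts$a10, counts$a11)
  i <- c(0L, 0L, 1L, 1L)
  j <- c(0L, 1L, 0L, 1L)
  n_a <- c(counts$a00 + counts$a01, counts$a10 + counts$a11)[i + 1L]
  n_b <- c(counts$a00 + counts$a10, counts$a01 + counts$a11)[j + 1L]
  expected <- n_a * n_b / counts$total
  undefined <- expected == 0
  s <- ifelse(undefined, 0, (expected - a) / sqrt(expected))
  p <- ifelse(n_a == 0 | n_b == 0, NA_real_,
              (a / n_a + a / n_b) / 2)
  tibble::tibble(
    quadrant = sprintf("%d%d", i, j), i = i, j = j, n = a,
    expected = expected, s = s, p = p, undefined = undefined
  )
}

#' Sparsity statistic of a single quadrant
#'
#' @inheritParams quadrant_stats
#' @param i,j Quadrant indices in `{0, 1}`; `i` indexes probe A's call,
#'   `j` probe B's.
#' @return A one-row tibble (see [quadrant_stats()]).
#' @export
sparsity_stat <- function(counts, i, j) {
  stopifnot(i %in% 0:1, j %in% 0:1)
  stats <- quadrant_stats(counts)
  stats[stats$i == i & stats$j == j, ]
}

RELATIONS <- c("EQUIVALENT", "OPPOSITE", "LOW_LOW", "LOW_HIGH",
               "HIGH_HIGH", "HIGH_LOW", "NONE")

# Map of the single sparse quadrant to the asymmetric relation it implies:
# sparse (0,0): A low => B high, (0,1): A low => B low,
# (1,0): A high => B high, (1,1): A high => B low.
ASYMMETRIC_BY_QUADRANT <- c(`00` = "LOW_HIGH", `01` = "LOW_LOW",
                            `10` = "HIGH_HIGH", `11` = "HIGH_LOW")

#' Classify a probe pair into a Boolean implication relation
#'
#' A quadrant is sparse when its statistic exceeds `s_threshold` and its
#' error rate is below `p_threshold` (strict inequalities). Both off-diagonal
#' quadrants sparse gives EQUIVALENT, both diagonal quadrants OPPOSITE;
#' exactly one sparse quadrant gives the corresponding asymmetric relation.
#' Pairs with fewer than `min_total` informative samples, with no sparse
#' quadrant, or with an undefined sparse pattern (two adjacent, or three or
#' more sparse quadrants) are classified NONE; the latter carries an
#' `"ambiguous"` flag.
#'
#' @inheritParams quadrant_stats
#' @param s_threshold Sparsity statistic threshold (default 3; raise to 50
#'   for stricter networks).
#' @param p_threshold Error-rate threshold (default 0.1).
#' @param min_total Minimum number of informative samples; below it the
#'   pair is NONE (guards against tiny-sample artifacts).
#' @return An object of class `boolean_implication`: list with `relation`,
#'   `stats` (the [quadrant_stats()] tibble), `counts`, thresholds and a
#'   diagnostic `flag`.
#' @examples
#' classify_pair(new_quadrant_counts(50, 0, 0, 50))$relation # EQUIVALENT
#' @export
classify_pair <- function(counts, s_threshold = 3, p_threshold = 0.1,
                          min_total = 20) {
  stopifnot(inherits(counts, "quadrant_counts"),
            s_threshold > 0, p_threshold > 0, p_threshold < 1)
  if (counts$total == 0 || counts$total < min_total) {
    return(new_implication("NONE", NULL, counts, s_threshold, p_threshold,
                           min_total, flag = "low_total"))
  }
  stats <- quadrant_stats(counts)
  sparse <- !stats$undefined & !is.na(stats$p) &
    stats$s > s_threshold & stats$p < p_threshold
  qs <- stats$quadrant[sparse]
  relation <- if (length(qs) == 2 && setequal(qs, c("01", "10"))) {
    "EQUIVALENT"
  } else if (length(qs) == 2 && setequal(qs, c("00", "11"))) {
    "OPPOSITE"
  } else if (length(qs) == 1) {
    ASYMMETRIC_BY_QUADRANT[[qs]]
  } else {
    "NONE"
  }
  flag <- if (relation == "NONE" && length(qs) >= 2) "ambiguous" else "ok"
  new_implication(relation, stats, counts, s_threshold, p_threshold,
                  min_total, flag)
}

new_implication <- function(relation, stats, counts, s_threshold,
                            p_threshold, min_total, flag) {
  structure(
    list(relation = relation, stats = stats, counts = counts,
         s_threshold = s_threshold, p_threshold = p_threshold,
         min_total = min_total, flag = flag),
    class = "boolean_implication"
  )
}

#' @export
print.boolean_implication <- function(x, ...) {
  cat("Boolean implication:", x$relation,
      if (x$flag != "ok") paste0("(", x$flag, ")"), "\n")
  print(x$counts)
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' @export
tidy.boolean_implication <- function(x, ...) {
  base <- tibble::tibble(
    relation = x$relation, flag = x$flag, total = x$counts$total,
    a00 = x$counts$a00, a01 = x$counts$a01,
    a10 = x$counts$a10, a11 = x$counts$a11
  )
  if (is.null(x$stats)) return(base)
  wide <- tidyr::pivot_wider(
    x$stats[, c("quadrant", "s", "p")],
    names_from = "quadrant", values_from = c("s", "p")
  )
  dplyr::bind_cols(base, wide)
}

#' Boolean implication between two probes of an expression matrix
#'
#' Booleanizes (or reuses supplied calls), counts quadrants and classifies.
#'
#' @param x Expression matrix or a `boolean_calls` object.
#' @param probe_a,probe_b Probe ids (rownames of the matrix).
#' @param margin Noise margin used when `x` is an expression matrix.
#' @inheritParams classify_pair
#' @return A `boolean_implication` object.
#' @export
probe_implication <- function(x, probe_a, probe_b, s_threshold = 3,
                              p_threshold = 0.1, min_total = 20,
                              margin = 0.5) {
  calls <- if (inherits(x, "boolean_calls")) x else booleanize(x, margin)
  missing_ids <- setdiff(c(probe_a, probe_b), rownames(calls$calls))
  if (length(missing_ids) > 0) {
    stop("unknown probe id(s): ", paste(missing_ids, collapse = ", "))
  }
  counts <- quadrant_counts(calls$calls[probe_a, ], calls$calls[probe_b, ])
  classify_pair(counts, s_threshold, p_threshold, min_total)
}

#' Find all probes Boolean-equivalent to each query probe
#'
#' Vectorised scan of every probe in the call matrix against each query.
#' A probe is returned when the pair's off-diagonal quadrants (and only
#' those) are sparse at the configured thresholds. Self-matches are
#' excluded. The result does not depend on evaluation order.
#'
#' @param calls A `boolean_calls` object (or its integer call matrix).
#' @param query_probes Character vector of probe ids to scan from.
#' @inheritParams classify_pair
#' @return Named list: for each query probe, a character vector of
#'   equivalent probe ids.
#' @export
scan_equivalents <- function(calls, query_probes, s_threshold = 3,
                             p_threshold = 0.1, min_total = 20) {
  cm <- if (inherits(calls, "boolean_calls")) calls$calls else calls
  missing_ids <- setdiff(query_probes, rownames(cm))
  if (length(missing_ids) > 0) {
    stop("unknown query probe id(s): ", paste(missing_ids, collapse = ", "))
  }
  low <- cm == CALL_LOW
  high <- cm == CALL_HIGH
  low[is.na(low)] <- FALSE
  high[is.na(high)] <- FALSE
  storage.mode(low) <- "double"
  storage.mode(high) <- "double"

  out <- lapply(query_probes, function(q) {
    lq <- low[q, ]
    hq <- high[q, ]
    # First index = query probe's call, second = other probe's call.
    a00 <- drop(low %*% lq)
    a01 <- drop(high %*% lq)
    a10 <- drop(low %*% hq)
    a11 <- drop(high %*% hq)
    total <- a00 + a01 + a10 + a11
    n_q_low <- a00 + a01
    n_q_high <- a10 + a11
    n_o_low <- a00 + a10
    n_o_high <- a01 + a11
    sparse <- function(a, n_first, n_second) {
      expected <- n_first * n_second / total
      ok <- total > 0 & expected > 0
      s <- ifelse(ok, (expected - a) / sqrt(pmax(expected, 1e-300)), 0)
      p <- ifelse(ok, (a / n_first + a / n_second) / 2, NA_real_)
      ok & s > s_threshold & !is.na(p) & p < p_threshold
    }
    s00 <- sparse(a00, n_q_low, n_o_low)
    s01 <- sparse(a01, n_q_low, n_o_high)
    s10 <- sparse(a10, n_q_high, n_o_low)
    s11 <- sparse(a11, n_q_high, n_o_high)
    eq <- total >= min_total & s01 & s10 & !s00 & !s11
    setdiff(rownames(cm)[eq], q)
  })
  names(out) <- query_probes
  out
}
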