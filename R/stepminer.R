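#' Fit a rising one-step function to a vector of expression values
#'
#' Sorts the values ascending (unless `already_sorted`) and fits a step
#' function with a single upward transition: samples `1..k` are modelled by
#' their mean (`mu_low`), samples `k+1..n` by theirs (`mu_high`). All `n - 1`
#' step positions are evaluated via prefix sums and the position minimising
#' the residual sum of squares is kept; ties on the SSE are broken by the
#' smallest `k`. The midpoint `(mu_low + mu_high) / 2` is the StepMiner
#' threshold used downstream to binarise expression.
#'
#' The adaptive-regression F statistic
#' `fstat = (ssr / (m - 1)) / (sse / (n - m))` is reported for diagnostics;
#' `m` is the number of fitted parameters (two segment means plus the step
#' position, so 3 by default). A perfectly fitted step (`sse = 0`) reports
#' `fstat = Inf`; a constant vector additionally sets the `degenerate` flag.
#'
#' @param values Numeric vector of (log2-scale) expression values. Missing
#'   values are dropped before fitting.
#' @param already_sorted Set `TRUE` when `values` is known to be sorted
#'   ascending, to skip the sort.
#' @param m Degrees of freedom of the fit used in the F statistic.
#' @return An object of class `step_fit`: a list with elements `n`, `k`,
#'   `mu_low`, `mu_high`, `threshold`, `sse`, `ssr`, `m`, `fstat`,
#'   `degenerate`.
#' @examples
#' fit_step(c(1, 1, 1, 5, 5, 5))
#' @export
fit_step <- function(values, already_sorted = FALSE, m = 3) {
  x <- unname(values[!is.na(values)])
  if (any(!is.finite(x))) stop("fit_step() requires finite values")
  n <- length(x)
  if (n < 2) stop("fit_step() needs at least 2 non-missing values, got ", n)
  if (!already_sorted) x <- sort(x)

  tot <- sum(x)
  xbar <- tot / n

  if (x[n] - x[1] == 0) {
    return(new_step_fit(n, 1L, x[1], x[1], sse = 0, ssr = 0, m = m,
                        degenerate = TRUE))
  }

  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1L)
  sum_low <- cs[k]
  sum_high <- tot - sum_low
  mu_low <- sum_low / k
  mu_high <- sum_high / (n - k)
  # Per-segment SSE via sum(x^2) - segment mean identity; clamp tiny negatives.
  sse <- pmax((cs2[k] - sum_low^2 / k) +
                (cs2[n] - cs2[k] - sum_high^2 / (n - k)), 0)
  best <- which.min(sse) # first minimum = smallest k on ties
  ssr <- best * (mu_low[best] - xbar)^2 +
    (n - best) * (mu_high[best] - xbar)^2
  new_step_fit(n, as.integer(best), mu_low[best], mu_high[best],
               sse = sse[best], ssr = ssr, m = m, degenerate = FALSE)
}

new_step_fit <- function(n, k, mu_low, mu_high, sse, ssr, m, degenerate) {
  fstat <- if (sse == 0) {
    Inf
  } else if (n - m <= 0) {
    NA_real_
  } else {
    (ssr / (m - 1)) / (sse / (n - m))
  }
  structure(
    list(n = n, k = k, mu_low = mu_low, mu_high = mu_high,
         threshold = (mu_low + mu_high) / 2, sse = sse, ssr = ssr,
         m = m, fstat = fstat, degenerate = degenerate),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat("StepMiner one-step fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  step after k = %d: mu_low = %.4g, mu_high = %.4g\n",
              x$k, x$mu_low, x$mu_high))
  cat(sprintf("  threshold = %.4g, sse = %.4g, F = %.4g%s\n",
              x$threshold, x$sse, x$fstat,
              if (x$degenerate) " (degenerate: constant input)" else ""))
  invisible(x)
}

#' @export
tidy.step_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, mu_low = x$mu_low, mu_high = x$mu_high,
    threshold = x$threshold, sse = x$sse, ssr = x$ssr,
    fstat = x$fstat, degenerate = x$degenerate
  )
}

#' Plot a step fit over the sorted values it was fitted to
#'
#' @param object A `step_fit`.
#' @param values The values the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.step_fit <- function(object, values, ...) {
  x <- sort(values[!is.na(values)])
  df <- tibble::tibble(
    rank = seq_along(x), value = x,
    fitted = c(rep(object$mu_low, object$k),
               rep(object$mu_high, length(x) - object$k))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "sample rank", y = "log2 expression",
                  title = "One-step fit and StepMiner threshold")
}

#' StepMiner threshold of a probe's expression values
#'
#' Midpoint of the two segment means of the best rising one-step fit.
#'
#' @inheritParams fit_step
#' @return A single numeric threshold.
#' @examples
#' step_threshold(c(1, 1, 1, 5, 5, 5)) # 3
#' @export
step_threshold <- function(values) {
  fit_step(values)$threshold
}

#' Convert an expression matrix to ternary Boolean calls
#'
#' Each probe (row) gets a StepMiner threshold; values below
#' `threshold - margin` are called LOW, above `threshold + margin` HIGH, and
#' everything else (including values exactly on the margin boundaries)
#' INTERMEDIATE. The default margin of 0.5 log2 units corresponds to a
#' twofold-change noise band around the threshold. Missing values stay
#' missing and are flagged separately from INTERMEDIATE.
#'
#' @param expr Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param margin Non-negative noise margin in log2 units.
#' @return An object of class `boolean_calls`: list with `calls` (integer
#'   matrix coded 0 = LOW, 1 = HIGH, 2 = INTERMEDIATE, NA = missing),
#'   `thresholds` (named per-probe vector) and `margin`.
#' @examples
#' m <- rbind(p1 = c(1, 1, 5, 5))
#' booleanize(m, margin = 0.5)$calls
#' @export
booleanize <- function(expr, margin = 0.5) {
  stopifnot(is.matrix(expr))
  if (margin < 0) stop("margin must be >= 0")
  if (is.null(rownames(expr))) stop("expr must have probe ids as rownames")

  thresholds <- vapply(seq_len(nrow(expr)), function(i) {
    v <- expr[i, ]
    if (sum(!is.na(v)) < 2) NA_real_ else fit_step(v)$threshold
  }, numeric(1))
  names(thresholds) <- rownames(expr)

  calls <- matrix(CALL_INTERMEDIATE, nrow = nrow(expr), ncol = ncol(expr),
                  dimnames = dimnames(expr))
  lo <- expr < (thresholds - margin)
  hi <- expr > (thresholds + margin)
  calls[which(lo)] <- CALL_LOW
  calls[which(hi)] <- CALL_HIGH
  calls[is.na(expr) | is.na(thresholds)[row(expr)]] <- NA_integer_

  structure(list(calls = calls, thresholds = thresholds, margin = margin),
            class = "boolean_calls")
}

#' @export
print.boolean_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c(0, 1, 2), exclude = NULL,
                      labels = c("LOW", "HIGH", "INTERMEDIATE")),
               useNA = "ifany")
  cat("Boolean calls: ", nrow(x$calls), " probes x ", ncol(x$calls),
      " samples (margin ", x$margin, ")\n", sep = "")
  print(tab)
  invisible(x)
}

# Human-readable labels for a call vector or matrix.
call_labels <- function(calls) {
  out <- array(NA_character_, dim = dim(calls) %||% length(calls),
               dimnames = dimnames(calls))
  out[calls == CALL_LOW] <- "0"
  out[calls == CALL_HIGH] <- "1"
  out[calls == CALL_INTERMEDIATE] <- "I"
  out[is.na(calls)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
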