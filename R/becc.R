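#' BECC run configuration
#'
#' Bundles the tunable parameters of a [run_becc()] pipeline run.
#'
#' @param seed_probe Probe id the equivalence expansion starts from.
#' @param s_threshold Sparsity statistic threshold for Boolean equivalence
#'   (default 3; raise to 50 for stricter, more specific networks).
#' @param p_threshold Error-rate threshold (default 0.1).
#' @param expansion_steps Number of equivalence-expansion rounds (default 3;
#'   further rounds tend to accumulate noise).
#' @param noise_margin Log2 noise margin around each StepMiner threshold
#'   (default 0.5, a twofold-change band).
#' @param null_pairs Number of random probe pairs for the empirical null
#'   (default 100000).
#' @param min_informative Minimum informative samples for a pair to be
#'   classified (default 20).
#' @param rng_seed Integer seed driving the null-pair sampling; `NULL`
#'   leaves the RNG state alone.
#' @return A `becc_config` object.
#' @export
becc_config <- function(seed_probe, s_threshold = 3, p_threshold = 0.1,
                        expansion_steps = 3, noise_margin = 0.5,
                        null_pairs = 1e5, min_informative = 20,
                        rng_seed = NULL) {
  stopifnot(is.character(seed_probe), length(seed_probe) == 1)
  if (s_threshold <= 0) stop("s_threshold must be > 0")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  if (expansion_steps < 1) stop("expansion_steps must be >= 1")
  if (noise_margin < 0) stop("noise_margin must be >= 0")
  structure(
    list(seed_probe = seed_probe, s_threshold = s_threshold,
         p_threshold = p_threshold, expansion_steps = expansion_steps,
         noise_margin = noise_margin, null_pairs = null_pairs,
         min_informative = min_informative, rng_seed = rng_seed),
    class = "becc_config"
  )
}

#' Expand a seed probe through rounds of Boolean equivalence
#'
#' Round 1 collects every probe Boolean-equivalent to the seed (set A);
#' each later round adds probes equivalent to at least one member of the
#' previous set (sets B, C, ...). The seed itself is excluded from the sets;
#' the final candidate list `L` is the last set plus the seed. Set sizes are
#' reported per round via `message()`.
#'
#' @param calls A `boolean_calls` object.
#' @param seed_probe Probe id to start from; it must have both LOW and HIGH
#'   calls (a probe booleanized to one side carries no implication signal).
#' @param steps Number of expansion rounds.
#' @inheritParams classify_pair
#' @param verbose Emit per-round set sizes.
#' @return An `expansion_trace`: list with `seed`, `sets` (cumulative
#'   character vectors per round), `sizes`, and `candidates` (= L).
#' @export
expand_seed <- function(calls, seed_probe, steps = 3, s_threshold = 3,
                        p_threshold = 0.1, min_total = 20, verbose = TRUE) {
  cm <- calls$calls
  if (!seed_probe %in% rownames(cm)) {
    stop("seed probe ", seed_probe, " not present in the matrix")
  }
  seed_calls <- cm[seed_probe, ]
  if (!any(seed_calls == CALL_LOW, na.rm = TRUE) ||
      !any(seed_calls == CALL_HIGH, na.rm = TRUE)) {
    stop("seed probe ", seed_probe, " is degenerate (no LOW/HIGH contrast); ",
         "choose a different seed probeset")
  }
  sets <- vector("list", steps)
  current <- character(0)
  frontier <- seed_probe
  for (step in seq_len(steps)) {
    found <- if (length(frontier) > 0) {
      scan_equivalents(calls, frontier, s_threshold, p_threshold, min_total)
    } else {
      list()
    }
    new_probes <- setdiff(unique(unlist(found)), seed_probe)
    expanded <- union(current, new_probes)
    frontier <- setdiff(expanded, current)
    current <- sort(expanded)
    sets[[step]] <- current
    if (verbose) {
      message("expansion step ", step, ": ", length(current), " probes")
    }
    if (step == 1 && length(current) == 0) {
      warning("seed probe ", seed_probe,
              " has no Boolean-equivalent probes; returning empty result")
      sets[seq_len(steps)] <- list(character(0))
      break
    }
  }
  names(sets) <- if (steps <= 3) LETTERS[seq_len(steps)] else
    paste0("step", seq_len(steps))
  structure(
    list(seed = seed_probe, sets = sets,
         sizes = vapply(sets, length, integer(1)),
         candidates = union(sets[[steps]], seed_probe)),
    class = "expansion_trace"
  )
}

#' @export
print.expansion_trace <- function(x, ...) {
  cat("BECC expansion from seed", x$seed, "\n")
  for (nm in names(x$sets)) {
    cat("  set ", nm, ": ", length(x$sets[[nm]]), " probes\n", sep = "")
  }
  cat("  L (candidates incl. seed):", length(x$candidates), "\n")
  invisible(x)
}

#' Correlation/slope score of a probe pair
#'
#' Pearson correlation `r` and a symmetrized regression slope `s` combined
#' as `score = r^2 + s^2`. The slope is computed in both orientations
#' (second probe on first, and vice versa), each replaced by its reciprocal
#' when above 1, and the smaller of the two is kept, so the score does not
#' depend on argument order. Negative correlations and slopes are floored at
#' 0 before squaring, so anti-correlated pairs score near 0. The score lies
#' in `[0, 2]`; a probe against itself scores exactly 2.
#'
#' @param values_a,values_b Numeric vectors over the same ordered samples;
#'   pairs with a missing value in either member are dropped.
#' @return A one-row tibble with `r`, `s`, `score`, `n`.
#' @examples
#' a <- c(1, 2, 3, 4, 5)
#' pair_score(a, 2 * a) # r = 1, s = 1/2, score = 1.25
#' @export
pair_score <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("value vectors differ in length")
  }
  keep <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[keep]
  b <- values_b[keep]
  if (length(a) < 3) stop("need at least 3 paired non-missing samples")
  va <- var(a)
  vb <- var(b)
  if (va == 0 || vb == 0) {
    stop("constant vector: correlation and slope are undefined")
  }
  cab <- cov(a, b)
  r <- max(cab / sqrt(va * vb), 0)
  s <- min(symmetrize_slope(cab / va), symmetrize_slope(cab / vb))
  tibble::tibble(r = r, s = s, score = r^2 + s^2, n = length(a))
}

symmetrize_slope <- function(s) {
  if (is.na(s) || s <= 0) 0 else min(s, 1 / s)
}

# Vectorised pair scores for index pairs (ii, jj) into the rows of X.
# Handles missing values through masks; returns NA for degenerate pairs.
pair_scores_idx <- function(X, ii, jj, chunk_size = 5000L) {
  scores <- numeric(length(ii))
  for (start in seq(1L, length(ii), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(ii))
    A <- X[ii[idx], , drop = FALSE]
    B <- X[jj[idx], , drop = FALSE]
    W <- (!is.na(A)) & (!is.na(B))
    A[!W] <- 0
    B[!W] <- 0
    n <- rowSums(W)
    sa <- rowSums(A)
    sb <- rowSums(B)
    vab <- rowSums(A * B) / n - (sa / n) * (sb / n)
    va <- rowSums(A * A) / n - (sa / n)^2
    vb <- rowSums(B * B) / n - (sb / n)^2
    ok <- n >= 3 & va > 0 & vb > 0
    r <- ifelse(ok, pmax(vab / sqrt(va * vb), 0), NA_real_)
    s1 <- vab / va
    s2 <- vab / vb
    sym <- function(s) ifelse(s <= 0, 0, pmin(s, 1 / s))
    s <- ifelse(ok, pmin(sym(s1), sym(s2)), NA_real_)
    scores[idx] <- r^2 + s^2
  }
  scores
}

#' Pairwise score matrix over a candidate list
#'
#' Symmetric `length(probes)` square matrix of [pair_score()] values with
#' the diagonal set to 2 (self-score). Each unordered pair is computed once.
#'
#' @param expr Expression matrix (probes in rows).
#' @param probes Character vector of probe ids (the candidate list L).
#' @return A numeric matrix with `probes` as dimnames.
#' @export
score_matrix <- function(expr, probes) {
  missing_ids <- setdiff(probes, rownames(expr))
  if (length(missing_ids) > 0) {
    stop("probes absent from the matrix: ", paste(missing_ids, collapse = ", "))
  }
  n <- length(probes)
  M <- diag(2, n)
  dimnames(M) <- list(probes, probes)
  if (n < 2) return(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  sub <- expr[probes, , drop = FALSE]
  sc <- pair_scores_idx(sub, pairs[, 1], pairs[, 2])
  M[pairs] <- sc
  M[pairs[, c(2, 1), drop = FALSE]] <- sc
  M
}

#' Rank-weighted gene scores from a score matrix
#'
#' Each row of `M` (including its diagonal self-score) is sorted ascending
#' and dotted with the rank vector `0, 1, ..., len(L) - 1`:
#' `gs_i = (1 / len(L)) * sum_k k * score_ik / 2` where `score_ik` is the
#' k-th smallest score in row i. Scores of probes tightly co-expressed with
#' the whole list approach the upper bound `(len(L) - 1) / 2`.
#'
#' @param M Square score matrix (see [score_matrix()]).
#' @return Named numeric vector of gene scores, one per row of `M`.
#' @export
gene_scores <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  n <- ncol(M)
  ranks <- seq_len(n) - 1
  gs <- apply(M, 1, function(row) sum(ranks * sort(row) / 2) / n)
  names(gs) <- rownames(M)
  gs
}

#' StepMiner threshold on a gene-score vector
#'
#' Fits the rising one-step function to the sorted scores and selects the
#' probes strictly above the step midpoint. A constant score vector is
#' degenerate: everything is selected, with a warning.
#'
#' @param gs Named numeric vector of gene scores.
#' @return List with `threshold`, `selected` (probe ids), `fit` (the
#'   [fit_step()] object or `NULL`) and `degenerate`.
#' @export
select_by_threshold <- function(gs) {
  if (length(gs) < 2) stop("need at least 2 gene scores")
  if (max(gs) - min(gs) == 0) {
    warning("gene scores are constant; selecting all probes")
    return(list(threshold = gs[[1]], selected = names(gs), fit = NULL,
                degenerate = TRUE))
  }
  fit <- fit_step(gs)
  list(threshold = fit$threshold,
       selected = names(gs)[gs > fit$threshold],
       fit = fit, degenerate = FALSE)
}

#' Empirical random-pair null for gene scores
#'
#' Samples distinct probe pairs uniformly (without replacement) from the
#' whole matrix, computes their pair scores, and converts the score moments
#' to the null mean and spread of a gene score over a candidate list of
#' length `len_l`: `E[gs] = E[score] * (len_l - 1) / 4` and
#' `sd(gs) = sqrt(Var[score]) * (len_l - 1) / 4`. When a selection
#' `threshold` is supplied, a one-sided upper-tail Z-test of the threshold
#' against this null is reported. Both conversions treat the sorted scores
#' in a row as exchangeable draws and are approximations (see the methods
#' vignette).
#'
#' @param expr Expression matrix (probes in rows).
#' @param len_l Length of the candidate list the null is scaled to.
#' @param n_pairs Number of random pairs (at least 1000; capped at the
#'   number of distinct pairs, in which case all pairs are used).
#' @param rng_seed Integer seed for the pair sampling; `NULL` uses the
#'   current RNG state.
#' @param threshold Optional gs threshold to test.
#' @return A `becc_null` object: list with `mean_score`, `var_score`,
#'   `e_gs`, `sd_gs`, `n_pairs`, `n_dropped`, `rng_seed`, `scores`,
#'   `threshold`, `z`, `p_value`.
#' @export
empirical_null <- function(expr, len_l, n_pairs = 1e5, rng_seed = NULL,
                           threshold = NULL) {
  np <- nrow(expr)
  if (np < 2) stop("need at least 2 probes to sample pairs")
  if (n_pairs < 1000) stop("n_pairs must be at least 1000")
  total_pairs <- np * (np - 1) / 2
  n_pairs <- min(n_pairs, total_pairs)

  idx <- with_rng_seed(rng_seed, {
    if (n_pairs >= total_pairs) seq_len(total_pairs)
    else sort(sample.int(total_pairs, n_pairs))
  })
  # Decode linear pair index t into (i, j), i < j, lexicographic order.
  cum <- cumsum((np - 1):1)
  i <- findInterval(idx - 1, c(0, cum[-length(cum)]))
  j <- i + (idx - c(0, cum)[i])

  scores <- pair_scores_idx(expr, i, j)
  dropped <- sum(is.na(scores))
  scores <- scores[!is.na(scores)]
  mean_score <- mean(scores)
  var_score <- var(scores)
  e_gs <- mean_score * (len_l - 1) / 4
  sd_gs <- sqrt(var_score) * (len_l - 1) / 4
  z <- p_value <- NULL
  if (!is.null(threshold)) {
    z <- (threshold - e_gs) / sd_gs
    p_value <- pnorm(z, lower.tail = FALSE)
  }
  structure(
    list(mean_score = mean_score, var_score = var_score, e_gs = e_gs,
         sd_gs = sd_gs, len_l = len_l, n_pairs = length(scores),
         n_dropped = dropped, rng_seed = rng_seed, scores = scores,
         threshold = threshold, z = z, p_value = p_value),
    class = "becc_null"
  )
}

#' @export
print.becc_null <- function(x, ...) {
  cat(sprintf("Empirical null from %d random pairs: E[score] = %.4g, sd = %.4g\n",
              x$n_pairs, x$mean_score, sqrt(x$var_score)))
  cat(sprintf("  E[gs] = %.4g, sd(gs) = %.4g (len L = %d)\n",
              x$e_gs, x$sd_gs, x$len_l))
  if (!is.null(x$z)) {
    cat(sprintf("  threshold %.4g: Z = %.3g, one-sided p = %.3g\n",
                x$threshold, x$z, x$p_value))
  }
  invisible(x)
}

#' Run the full BECC pipeline
#'
#' Booleanizes the matrix, expands the seed probe through
#' `expansion_steps` rounds of Boolean equivalence, scores every candidate
#' pair by correlation and slope, rank-weights the scores into per-probe
#' gene scores, thresholds them with a step fit, and calibrates the
#' threshold against an empirical random-pair null. Probe ids are mapped to
#' gene symbols when an annotation is supplied.
#'
#' @param expr Expression matrix, probes in rows, log2 scale.
#' @param config A [becc_config()] object.
#' @param annotation Optional probe annotation tibble as returned by
#'   [read_annotation()] (columns `probe_id`, `symbols`).
#' @return A `becc_result` object; see [tidy.becc_result()] and
#'   [glance.becc_result()] for tabular views.
#' @export
run_becc <- function(expr, config, annotation = NULL) {
  stopifnot(inherits(config, "becc_config"))
  calls <- booleanize(expr, config$noise_margin)
  trace <- expand_seed(calls, config$seed_probe,
                       steps = config$expansion_steps,
                       s_threshold = config$s_threshold,
                       p_threshold = config$p_threshold,
                       min_total = config$min_informative)
  if (length(trace$candidates) < 2) {
    return(new_becc_result(config, trace, M = NULL, scores = empty_scores(),
                           threshold = NA_real_, null = NULL,
                           status = "empty: seed has no Boolean equivalents"))
  }
  L <- trace$candidates
  M <- score_matrix(expr, L)
  gs <- gene_scores(M)
  sel <- select_by_threshold(gs)
  null <- empirical_null(expr, len_l = length(L),
                         n_pairs = config$null_pairs,
                         rng_seed = config$rng_seed,
                         threshold = sel$threshold)
  message("candidates: ", length(L), "; selected: ", length(sel$selected))

  probe_ids <- names(gs)
  scores <- tibble::tibble(
    probe_id = probe_ids,
    gene_symbols = map_symbols(probe_ids, annotation),
    gs = unname(gs),
    selected = probe_ids %in% sel$selected,
    dynamic_range = unname(apply(expr[probe_ids, , drop = FALSE], 1,
                                 function(v) diff(range(v, na.rm = TRUE))))
  )
  scores <- dplyr::arrange(scores, dplyr::desc(.data$gs), .data$probe_id)
  scores$rank <- seq_len(nrow(scores))
  new_becc_result(config, trace, M, scores, sel$threshold, null, "ok")
}

empty_scores <- function() {
  tibble::tibble(probe_id = character(0), gene_symbols = character(0),
                 gs = numeric(0), selected = logical(0),
                 dynamic_range = numeric(0), rank = integer(0))
}

map_symbols <- function(probe_ids, annotation) {
  if (is.null(annotation)) return(rep(NA_character_, length(probe_ids)))
  idx <- match(probe_ids, annotation$probe_id)
  vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    syms <- annotation$symbols[[i]]
    if (length(syms) == 0) NA_character_ else paste(syms, collapse = " /// ")
  }, character(1))
}

new_becc_result <- function(config, trace, M, scores, threshold, null,
                            status) {
  structure(
    list(config = config, trace = trace, score_matrix = M, scores = scores,
         threshold = threshold, null = null, status = status),
    class = "becc_result"
  )
}

#' Selected unique gene symbols of a BECC result
#'
#' @param result A `becc_result`.
#' @return Character vector of deduplicated symbols of the selected probes
#'   (annotated probes only).
#' @export
selected_genes <- function(result) {
  stopifnot(inherits(result, "becc_result"))
  syms <- result$scores$gene_symbols[result$scores$selected]
  unique(unlist(strsplit(syms[!is.na(syms)], " /// ", fixed = TRUE)))
}

#' @export
print.becc_result <- function(x, ...) {
  cat("BECC result (seed ", x$config$seed_probe, ", status: ", x$status,
      ")\n", sep = "")
  if (x$status != "ok") return(invisible(x))
  print(x$trace)
  cat(sprintf("  gs threshold = %.4g; %d of %d probesets selected\n",
              x$threshold, sum(x$scores$selected), nrow(x$scores)))
  if (!is.null(x$null)) {
    cat(sprintf("  null Z = %.3g, one-sided p = %.3g\n",
                x$null$z, x$null$p_value))
  }
  print(head(x$scores, 10))
  invisible(x)
}

#' Tidy the per-probeset table of a BECC result
#'
#' @param x A `becc_result`.
#' @param ... Unused.
#' @return Tibble with one row per candidate probeset: `probe_id`,
#'   `gene_symbols`, `gs`, `rank`, `selected`, `dynamic_range`.
#' @export
tidy.becc_result <- function(x, ...) {
  x$scores[, c("probe_id", "gene_symbols", "gs", "rank", "selected",
               "dynamic_range")]
}

#' One-row summary of a BECC result
#'
#' @param x A `becc_result`.
#' @param ... Unused.
#' @return One-row tibble with expansion set sizes, threshold, null Z and
#'   p-value, and selection counts.
#' @export
glance.becc_result <- function(x, ...) {
  tibble::tibble(
    seed_probe = x$config$seed_probe,
    status = x$status,
    n_set_a = if (length(x$trace$sizes) >= 1) x$trace$sizes[[1]] else NA_integer_,
    n_set_b = if (length(x$trace$sizes) >= 2) x$trace$sizes[[2]] else NA_integer_,
    n_set_c = if (length(x$trace$sizes) >= 3) x$trace$sizes[[3]] else NA_integer_,
    len_l = length(x$trace$candidates),
    gs_threshold = x$threshold,
    n_selected = sum(x$scores$selected),
    n_genes = length(selected_genes(x)),
    null_mean_score = if (is.null(x$null)) NA_real_ else x$null$mean_score,
    e_gs = if (is.null(x$null)) NA_real_ else x$null$e_gs,
    sd_gs = if (is.null(x$null)) NA_real_ else x$null$sd_gs,
    z = if (is.null(x$null)) NA_real_ else x$null$z,
    p_value = if (is.null(x$null)) NA_real_ else x$null$p_value
  )
}

#' Plot the ranked gene scores of a BECC result
#'
#' Sorted gene scores with the StepMiner selection threshold; selected
#' probesets are highlighted.
#'
#' @param object A `becc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.becc_result <- function(object, ...) {
  df <- object$scores
  if (nrow(df) == 0) stop("empty BECC result; nothing to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$probe_id, .data$gs),
                                   y = .data$gs,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "gene score (gs)",
                  title = paste("BECC gene scores, seed",
                                object$config$seed_probe))
}
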