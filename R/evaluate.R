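#' High-high co-expression fraction for a gene pair
#'
#' Thresholds each gene and reports the fraction of samples (or single
#' cells) in which both genes are strictly above their thresholds — the
#' co-expression statistic used to vet a marker pair on purified-cell or
#' single-cell data.
#'
#' Two threshold modes are available. `"midrange"` uses the midpoint of a
#' value range: by default the range of all observed values in the matrix
#' (`range_basis = "dataset"`), mirroring scatterplots whose axis limits —
#' and midpoint reference lines — are set from the range observed across
#' genes in the dataset; `range_basis = "gene"` uses each gene's own range,
#' and an explicit `range` overrides both. `"stepminer"` uses each gene's
#' one-step threshold.
#'
#' @param expr Expression matrix (genes/probes in rows).
#' @param gene_a,gene_b Row ids of the two genes.
#' @param mode Threshold mode, `"midrange"` or `"stepminer"`.
#' @param range_basis For midrange mode: `"dataset"` (default) or `"gene"`.
#' @param range Optional length-2 numeric range overriding `range_basis`.
#' @return A one-row tibble with the thresholds, the four quadrant counts
#'   (`n_low_low`, `n_low_high`, `n_high_low`, `n_high_high`), `n`, and
#'   `fraction_high_high`.
#' @export
high_high_fraction <- function(expr, gene_a, gene_b,
                               mode = c("midrange", "stepminer"),
                               range_basis = c("dataset", "gene"),
                               range = NULL) {
  mode <- match.arg(mode)
  range_basis <- match.arg(range_basis)
  missing_ids <- setdiff(c(gene_a, gene_b), rownames(expr))
  if (length(missing_ids) > 0) {
    stop("unknown gene id(s): ", paste(missing_ids, collapse = ", "))
  }
  a <- expr[gene_a, ]
  b <- expr[gene_b, ]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0) stop("no paired non-missing samples")

  midrange <- function(v, gene) {
    v <- v[!is.na(v)]
    if (max(v) - min(v) == 0) {
      stop("gene ", gene, " is constant: midrange threshold undefined")
    }
    (min(v) + max(v)) / 2
  }
  if (mode == "midrange") {
    if (!is.null(range)) {
      stopifnot(length(range) == 2)
      ta <- tb <- (range[1] + range[2]) / 2
    } else if (range_basis == "dataset") {
      ta <- tb <- midrange(as.vector(expr), "dataset")
    } else {
      ta <- midrange(a, gene_a)
      tb <- midrange(b, gene_b)
    }
  } else {
    ta <- step_threshold(a)
    tb <- step_threshold(b)
  }

  hh <- a > ta & b > tb
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b, mode = mode,
    threshold_a = ta, threshold_b = tb, n = length(a),
    n_low_low = sum(a <= ta & b <= tb),
    n_low_high = sum(a <= ta & b > tb),
    n_high_low = sum(a > ta & b <= tb),
    n_high_high = sum(hh),
    fraction_high_high = mean(hh)
  )
}

#' Scatterplot of a gene pair with its high-high thresholds
#'
#' @inheritParams high_high_fraction
#' @param ... Passed to [high_high_fraction()].
#' @return A ggplot object; samples above both thresholds are highlighted.
#' @export
plot_high_high <- function(expr, gene_a, gene_b, ...) {
  rep <- high_high_fraction(expr, gene_a, gene_b, ...)
  a <- expr[gene_a, ]
  b <- expr[gene_b, ]
  df <- tibble::tibble(a = a, b = b,
                       high_high = a > rep$threshold_a & b > rep$threshold_b)
  df <- df[!is.na(df$a) & !is.na(df$b), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   colour = .data$high_high)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = rep$threshold_a, colour = "red") +
    ggplot2::geom_hline(yintercept = rep$threshold_b, colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "orange",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = paste(gene_a, "(log2)"), y = paste(gene_b, "(log2)"),
      title = sprintf("%s vs %s: %.0f%% high-high", gene_a, gene_b,
                      100 * rep$fraction_high_high)
    ) +
    ggplot2::theme(legend.position = "none")
}

#' Variance-ratio F-test between a candidate and a reference gene
#'
#' Compares expression variability of two genes over the same sample set
#' with the classical two-sided F-test on the variance ratio (as computed by
#' [stats::var.test()]). The reported F statistic is the larger variance
#' over the smaller, so `f >= 1` with degrees of freedom `(n - 1, n - 1)`;
#' the p-value is orientation-free. A stable candidate biomarker shows a
#' significantly smaller standard deviation than a noisy reference on
#' purified-cell data.
#'
#' @param values_candidate,values_reference Numeric vectors over the same
#'   samples; pairs with a missing value in either are dropped.
#' @return A one-row tibble with `sd_candidate`, `sd_reference`, `f`,
#'   `df1`, `df2`, `p_value`, `degenerate`.
#' @export
variance_ftest <- function(values_candidate, values_reference) {
  if (length(values_candidate) != length(values_reference)) {
    stop("value vectors differ in length")
  }
  keep <- !is.na(values_candidate) & !is.na(values_reference)
  x <- values_candidate[keep]
  y <- values_reference[keep]
  if (length(x) < 3) stop("need at least 3 paired non-missing samples")
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 || vy == 0) {
    return(tibble::tibble(sd_candidate = sqrt(vx), sd_reference = sqrt(vy),
                          f = NA_real_, df1 = length(x) - 1L,
                          df2 = length(y) - 1L, p_value = NA_real_,
                          degenerate = TRUE))
  }
  vt <- stats::var.test(x, y)
  tibble::tibble(
    sd_candidate = sqrt(vx), sd_reference = sqrt(vy),
    f = max(vx, vy) / min(vx, vy),
    df1 = length(x) - 1L, df2 = length(y) - 1L,
    p_value = vt$p.value, degenerate = FALSE
  )
}

#' Rank candidate genes by Pearson correlation with a reference gene
#'
#' @param expr Expression matrix (genes/probes in rows).
#' @param reference_gene Row id of the reference.
#' @param candidate_genes Row ids to rank.
#' @return Tibble with `gene` and `r`, sorted by `r` descending (ties broken
#'   by gene id, undefined correlations placed last with `r = NA`).
#' @export
correlation_ranking <- function(expr, reference_gene, candidate_genes) {
  missing_ids <- setdiff(c(reference_gene, candidate_genes), rownames(expr))
  if (length(missing_ids) > 0) {
    stop("unknown gene id(s): ", paste(missing_ids, collapse = ", "))
  }
  ref <- expr[reference_gene, ]
  r <- vapply(candidate_genes, function(g) {
    v <- expr[g, ]
    keep <- !is.na(ref) & !is.na(v)
    if (sum(keep) < 3) stop("need at least 3 paired samples for ", g)
    if (var(v[keep]) == 0 || var(ref[keep]) == 0) return(NA_real_)
    cor(ref[keep], v[keep])
  }, numeric(1))
  out <- tibble::tibble(gene = candidate_genes, r = unname(r))
  dplyr::arrange(out, dplyr::desc(.data$r), .data$gene)
}
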