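#' Configuration for the synthetic expression compendium
#'
#' The generator emulates the structure a universal-marker search exploits
#' in a bulk compendium: a latent per-sample target-cell abundance; a
#' planted cluster of universal marker probes that are high exactly when
#' the sample contains target cells (so their log2 values are bimodal and
#' mutually Boolean-equivalent); planted subset markers that are high only
#' in the subset of target-high samples whose subset program is active
#' (yielding asymmetric "subset high implies universal high" geometry); and
#' independent bimodal noise probes.
#'
#' @param n_samples Number of samples (default 1000).
#' @param n_universal Number of universal marker probes (default 20; two
#'   probes per synthetic gene symbol).
#' @param n_subset Number of subset marker probes (default 10).
#' @param n_noise Number of unrelated noise probes (default 2000).
#' @param pure_fraction Fraction of samples that are pure target cells,
#'   abundance exactly 1 (default 0.02).
#' @param zero_fraction Fraction of samples with near-zero target content
#'   (default 0.6); the remainder draw abundance uniformly on (0.05, 1].
#' @param low_mean,high_mean Bimodal state means in log2 units (defaults 4
#'   and 9, the dynamic range typical of normalized arrays).
#' @param sd Within-state standard deviation in log2 units (default 0.7).
#' @param subset_prevalence Probability that a target-high sample also
#'   activates the subset program (default 0.4).
#' @param abundance_cutoff Abundance above which target-tracking probes are
#'   in the high state (default 0.05).
#' @param rng_seed Integer seed (default 1).
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_samples = 1000, n_universal = 20,
                             n_subset = 10, n_noise = 2000,
                             pure_fraction = 0.02, zero_fraction = 0.6,
                             low_mean = 4, high_mean = 9, sd = 0.7,
                             subset_prevalence = 0.4,
                             abundance_cutoff = 0.05, rng_seed = 1) {
  if (high_mean <= low_mean) stop("high_mean must exceed low_mean")
  if (sd <= 0) stop("sd must be > 0")
  if (subset_prevalence <= 0 || subset_prevalence >= 1) {
    stop("subset_prevalence must be in (0, 1)")
  }
  if (n_samples < 1 || n_universal < 1 || n_subset < 1 || n_noise < 1) {
    stop("counts must be positive")
  }
  if (pure_fraction < 0 || zero_fraction < 0 ||
      pure_fraction + zero_fraction >= 1) {
    stop("pure_fraction + zero_fraction must be below 1 and non-negative")
  }
  structure(
    list(n_samples = n_samples, n_universal = n_universal,
         n_subset = n_subset, n_noise = n_noise,
         pure_fraction = pure_fraction, zero_fraction = zero_fraction,
         low_mean = low_mean, high_mean = high_mean, sd = sd,
         subset_prevalence = subset_prevalence,
         abundance_cutoff = abundance_cutoff, rng_seed = rng_seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic expression compendium with planted ground truth
#'
#' @param config A [synthetic_config()] object.
#' @return A `synthetic_compendium`: list with `expr` (log2 matrix, probes
#'   in rows), `truth` (tibble: `probe_id`, `label` in
#'   universal/subset/noise, `gene_symbol`), `samples` (tibble: `sample_id`,
#'   `abundance`, `pure`, `target_high`, `subset_active`), `annotation`
#'   (tibble: `probe_id`, `symbols` list-column) and `config`. Identical
#'   configs (including seed) produce identical output.
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng_seed(config$rng_seed, {
    n <- config$n_samples
    u <- runif(n)
    abundance <- ifelse(
      u < config$pure_fraction, 1,
      ifelse(u < config$pure_fraction + config$zero_fraction,
             runif(n, 0, 0.02),
             runif(n, 0.05, 1))
    )
    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      abundance = abundance,
      pure = abundance >= 0.95,
      target_high = abundance > config$abundance_cutoff,
      subset_active = abundance > config$abundance_cutoff &
        runif(n) < config$subset_prevalence
    )
    expr <- build_expression(config, samples)
    truth <- probe_truth(config)
    structure(
      list(expr = expr, truth = truth, samples = samples,
           annotation = tibble::tibble(
             probe_id = truth$probe_id,
             symbols = as.list(truth$gene_symbol)
           ),
           config = config),
      class = "synthetic_compendium"
    )
  })
}

#' Generate a purified population (all-target or no-target samples)
#'
#' Emulates a purified-cell dataset: every sample has target-cell abundance
#' 1 (`population = "target"`) or 0 (`"other"`). Subset programs still
#' toggle per sample in the target population, so subset markers stay
#' bimodal there while universal markers are uniformly high.
#'
#' @param config A [synthetic_config()] object.
#' @param population `"target"` or `"other"`.
#' @param n_samples Number of samples (default 200).
#' @return A `synthetic_compendium` (see [generate_compendium()]).
#' @export
generate_pure_population <- function(config, population = c("target", "other"),
                                     n_samples = 200) {
  stopifnot(inherits(config, "synthetic_config"))
  population <- match.arg(population)
  with_rng_seed(config$rng_seed, {
    target <- population == "target"
    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      abundance = if (target) rep(1, n_samples) else rep(0, n_samples),
      pure = target,
      target_high = target,
      subset_active = target & runif(n_samples) < config$subset_prevalence
    )
    expr <- build_expression(config, samples)
    structure(
      list(expr = expr, truth = probe_truth(config), samples = samples,
           annotation = NULL, config = config),
      class = "synthetic_compendium"
    )
  })
}

# Bimodal emission: state matrix (probes x samples) -> log2 values.
emit <- function(state, config) {
  means <- ifelse(state, config$high_mean, config$low_mean)
  means + rnorm(length(means), sd = config$sd)
}

build_expression <- function(config, samples) {
  n <- nrow(samples)
  truth <- probe_truth(config)

  uni_state <- matrix(rep(samples$target_high, each = config$n_universal),
                      nrow = config$n_universal)
  sub_state <- matrix(rep(samples$subset_active, each = config$n_subset),
                      nrow = config$n_subset)
  mixing <- runif(config$n_noise, 0.05, 0.95)
  noise_state <- matrix(runif(config$n_noise * n), nrow = config$n_noise) <
    mixing

  expr <- rbind(
    matrix(emit(uni_state, config), nrow = config$n_universal),
    matrix(emit(sub_state, config), nrow = config$n_subset),
    matrix(emit(noise_state, config), nrow = config$n_noise)
  )
  dimnames(expr) <- list(truth$probe_id, samples$sample_id)
  expr
}

probe_truth <- function(config) {
  tibble::tibble(
    probe_id = c(sprintf("UNI%03d_at", seq_len(config$n_universal)),
                 sprintf("SUB%03d_at", seq_len(config$n_subset)),
                 sprintf("NSE%04d_at", seq_len(config$n_noise))),
    label = rep(c("universal", "subset", "noise"),
                c(config$n_universal, config$n_subset, config$n_noise)),
    gene_symbol = c(
      sprintf("UGENE%02d", ceiling(seq_len(config$n_universal) / 2)),
      sprintf("SGENE%02d", seq_len(config$n_subset)),
      sprintf("NGENE%04d", seq_len(config$n_noise))
    )
  )
}

#' @export
print.synthetic_compendium <- function(x, ...) {
  cat("Synthetic compendium: ", nrow(x$expr), " probes x ", ncol(x$expr),
      " samples\n", sep = "")
  print(table(x$truth$label))
  invisible(x)
}

#' Write a synthetic compendium to plain-text files
#'
#' Writes `matrix.tsv` (expression), `truth.tsv` (probe labels),
#' `samples.tsv` (latent sample state) and `annotation.tsv` (probe-to-gene
#' map with `Gene Symbol` column) into `dir`.
#'
#' @param compendium A `synthetic_compendium`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_compendium <- function(compendium, dir) {
  stopifnot(inherits(compendium, "synthetic_compendium"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    truth = file.path(dir, "truth.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv")
  )
  write_expression(compendium$expr, paths["matrix"])
  utils::write.table(compendium$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(compendium$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- data.frame(
    ID = compendium$truth$probe_id,
    `Gene Symbol` = compendium$truth$gene_symbol,
    check.names = FALSE
  )
  utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
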