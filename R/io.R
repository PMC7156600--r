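#' Read an expression matrix from a tab-delimited or series-matrix file
#'
#' `"tsv"` expects a header row of sample ids and probe ids in the first
#' column. `"series_matrix"` reads the table block between the standard
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers of a
#' GEO series-matrix file. Row and column order is preserved; non-numeric
#' cells (e.g. `"null"`) become missing values. Values are assumed already
#' normalized and log2-scaled; use `log2p1 = TRUE` for count-scale input.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param log2p1 Apply `log2(x + 1)` to the values after reading.
#' @return Numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns.
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix"),
                            log2p1 = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
      stop("no series_matrix table block ",
           "(!series_matrix_table_begin/end) found in ", path)
    }
    lines <- lines[(begin + 1):(end - 1)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("parse error at line 1: no data rows in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- gsub('^"|"$', "", cells[[1]])
  if (length(header) < 2) {
    stop("parse error at line 1: malformed header (expected probe id column ",
         "followed by sample ids)")
  }
  sample_ids <- header[-1]
  body <- cells[-1]
  widths <- lengths(body)
  bad <- which(widths != length(header))
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1] + 1, ": expected ", length(header),
         " fields, found ", widths[bad[1]])
  }
  tab <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
  probe_ids <- gsub('^"|"$', "", tab[, 1])
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup) > 0) {
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  values <- suppressWarnings(
    matrix(as.numeric(tab[, -1, drop = FALSE]), nrow = nrow(tab),
           dimnames = list(probe_ids, sample_ids))
  )
  if (log2p1) values <- log2(values + 1)
  values
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are printed with 17 significant digits so that
#' `read_expression(write_expression(m))` reproduces `m` exactly, including
#' missing entries (written as `NA`).
#'
#' @param expr Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  body <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  body[is.na(expr)] <- "NA"
  lines <- c(
    paste(c("ID_REF", colnames(expr)), collapse = "\t"),
    paste(rownames(expr), apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Tab-delimited platform table (GPL570-style) with a probe id column and a
#' gene symbol column; multi-symbol cells are split on `" /// "`. Probes
#' with an empty symbol cell map to zero symbols.
#'
#' @param path Path to the table.
#' @param probe_col,symbol_col Column headers (defaults `"ID"` and
#'   `"Gene Symbol"`).
#' @return Tibble with `probe_id` and a `symbols` list-column.
#' @export
read_annotation <- function(path, probe_col = "ID",
                            symbol_col = "Gene Symbol") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(c(probe_col, symbol_col), names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation is missing required column(s): ",
         paste(shQuote(missing_cols), collapse = ", "),
         " (expected headers ", shQuote(probe_col), " and ",
         shQuote(symbol_col), ")")
  }
  ids <- tab[[probe_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate probe id(s) in annotation: ", paste(dup, collapse = ", "))
  }
  symbols <- lapply(tab[[symbol_col]], function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, " /// ", fixed = TRUE)[[1]])
  })
  tibble::tibble(probe_id = ids, symbols = symbols)
}

#' Write a BECC result as a tab-delimited report
#'
#' One row per candidate probeset, sorted by gene score descending with
#' ties broken by probe id; the selection threshold and the Z-test against
#' the empirical null are recorded in `#`-prefixed header lines. Scores are
#' printed with 17 significant digits so they read back exactly.
#'
#' @param result A `becc_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_becc_results <- function(result, path) {
  stopifnot(inherits(result, "becc_result"))
  scores <- result$scores
  if (nrow(scores) == 0) {
    warning("empty BECC result: writing header-only report")
  }
  header <- c(
    sprintf("# seed_probe=%s", result$config$seed_probe),
    sprintf("# status=%s", result$status),
    sprintf("# gs_threshold=%.17g", result$threshold),
    if (!is.null(result$null)) c(
      sprintf("# null_z=%.17g", result$null$z),
      sprintf("# null_p_value=%.17g", result$null$p_value)
    ),
    paste(c("probe_id", "gene_symbols", "gs", "rank", "selected",
            "dynamic_range"), collapse = "\t")
  )
  rows <- if (nrow(scores) == 0) character(0) else {
    paste(scores$probe_id,
          ifelse(is.na(scores$gene_symbols), "", scores$gene_symbols),
          sprintf("%.17g", scores$gs),
          scores$rank,
          ifelse(scores$selected, "TRUE", "FALSE"),
          sprintf("%.17g", scores$dynamic_range),
          sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a BECC result report
#'
#' @param path Path written by [write_becc_results()].
#' @return Tibble with the report columns; threshold and Z-test values are
#'   attached as attributes `gs_threshold`, `null_z`, `null_p_value`.
#' @export
read_becc_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta_lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, "="), "", hit[1]))
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           check.names = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "logical", "numeric"))
  out <- tibble::as_tibble(tab)
  names(out)[1] <- "probe_id"
  attr(out, "gs_threshold") <- meta("gs_threshold")
  attr(out, "null_z") <- meta("null_z")
  attr(out, "null_p_value") <- meta("null_p_value")
  out
}

#' Write a Boolean call matrix as tab-delimited text
#'
#' Cells are `0` (LOW), `1` (HIGH), `I` (INTERMEDIATE) or `NA` (missing);
#' the per-probe StepMiner threshold is the second column.
#'
#' @param calls A `boolean_calls` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_boolean_calls <- function(calls, path) {
  stopifnot(inherits(calls, "boolean_calls"))
  labels <- call_labels(calls$calls)
  lines <- c(
    paste(c("probe_id", "threshold", colnames(calls$calls)), collapse = "\t"),
    paste(rownames(calls$calls),
          sprintf("%.17g", calls$thresholds),
          apply(labels, 1, paste, collapse = "\t"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
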