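#' Read a genes-by-samples TPM expression table
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Tab- and comma-separated files are auto-detected. Values must be
#' finite, non-negative numbers; duplicate gene or sample ids are rejected
#' with the offending id named.
#'
#' @param path Path to the expression table (TSV or CSV).
#' @param metadata_path Optional path to a sample-metadata table with columns
#'   `sample`, `condition`, `replicate`. When given, every expression sample
#'   must be described and the metadata is attached as the `"samples"`
#'   attribute (see [sample_info()]).
#' @return A tibble with `gene_id` and one numeric column per sample, in the
#'   input gene order.
#' @export
read_expression <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) abort_coexreg(sprintf("Expression file not found: %s", path))
  delim <- detect_delim(path)
  expr <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  names(expr)[1] <- "gene_id"
  expr$gene_id <- as.character(expr$gene_id)
  if (ncol(expr) < 2L) abort_coexreg("Expression table has no sample columns.")
  dup <- expr$gene_id[duplicated(expr$gene_id)]
  if (length(dup)) {
    abort_coexreg(sprintf("Duplicated gene id(s): %s.",
                          paste(unique(dup), collapse = ", ")))
  }
  dup_s <- names(expr)[-1][duplicated(names(expr)[-1])]
  if (length(dup_s)) {
    abort_coexreg(sprintf("Duplicated sample id(s): %s.",
                          paste(unique(dup_s), collapse = ", ")))
  }
  for (col in names(expr)[-1]) {
    v <- expr[[col]]
    if (!is.numeric(v)) {
      abort_coexreg(sprintf("Non-numeric values in sample column `%s`.", col))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      abort_coexreg(sprintf("Missing or non-finite values in sample column `%s`.", col))
    }
    if (any(v < 0)) {
      abort_coexreg(sprintf("Negative TPM values in sample column `%s`.", col))
    }
  }
  if (!is.null(metadata_path)) {
    samples <- read_sample_metadata(metadata_path)
    missing <- setdiff(names(expr)[-1], samples$sample)
    if (length(missing)) {
      abort_coexreg(sprintf("Sample(s) without metadata: %s.",
                            paste(missing, collapse = ", ")))
    }
    attr(expr, "samples") <- samples
  }
  expr
}

#' Read a sample-metadata table (sample, condition, replicate)
#' @param path Path to a TSV/CSV with columns `sample`, `condition`,
#'   `replicate`.
#' @return A tibble with those three columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort_coexreg(sprintf("Metadata file not found: %s", path))
  samples <- readr::read_delim(path, delim = detect_delim(path),
                               show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples))) {
    abort_coexreg(sprintf("Sample metadata must have columns %s.",
                          paste(need, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample)) {
    abort_coexreg("Duplicated sample ids in metadata.")
  }
  tibble::as_tibble(samples[need])
}

#' Retrieve sample metadata attached to an expression tibble
#' @param expr An expression tibble from [read_expression()].
#' @return The `samples` tibble, or `NULL` if none was attached.
#' @export
sample_info <- function(expr) attr(expr, "samples", exact = TRUE)

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an expression table (and optionally sample metadata) as TSV
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @param samples Optional samples tibble to write alongside.
#' @param metadata_path Output path for `samples` (required when given).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, samples = NULL, metadata_path = NULL) {
  readr::write_tsv(expr, path, progress = FALSE)
  if (!is.null(samples)) {
    if (is.null(metadata_path)) {
      abort_coexreg("`metadata_path` is required when writing sample metadata.")
    }
    readr::write_tsv(samples, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Filter transcripts that are unexpressed in most replicates of every condition
#'
#' A gene is removed iff, in *every* condition, the fraction of samples with
#' TPM exactly 0 exceeds `max_zero_fraction`. Genes expressed in at least one
#' condition are therefore retained, which keeps condition-specific
#' transcripts (e.g. cellulose-only CAZymes) in the network. Surviving genes
#' keep their input order, and the filter is idempotent.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param samples Samples tibble (`sample`, `condition`); defaults to the
#'   metadata attached by [read_expression()]. When absent, all samples are
#'   treated as one condition (a global filter).
#' @param max_zero_fraction A gene is dropped when its per-condition zero
#'   fraction exceeds this in every condition. Default 0.5 ("most replicates").
#' @return The filtered tibble; removed ids are in the `"removed_genes"`
#'   attribute (see [removed_genes()]).
#' @export
filter_low_expression <- function(expr, samples = sample_info(expr),
                                  max_zero_fraction = 0.5) {
  check_fraction(max_zero_fraction, "max_zero_fraction")
  if (!is.data.frame(expr) || nrow(expr) == 0L) {
    abort_coexreg("Cannot filter an empty expression table.")
  }
  m <- expr_matrix(expr)
  cond <- if (is.null(samples)) {
    rep("all", ncol(m))
  } else {
    samples$condition[match(colnames(m), samples$sample)]
  }
  if (anyNA(cond)) abort_coexreg("Some expression samples are missing from `samples`.")
  zero_frac <- vapply(unique(cond), function(cn) {
    rowMeans(m[, cond == cn, drop = FALSE] == 0)
  }, numeric(nrow(m)))
  zero_frac <- matrix(zero_frac, nrow = nrow(m))
  drop <- apply(zero_frac > max_zero_fraction, 1L, all)
  out <- expr[!drop, , drop = FALSE]
  attr(out, "samples") <- samples
  attr(out, "removed_genes") <- expr$gene_id[drop]
  out
}

#' Remove genes with zero variance across samples
#'
#' Pearson correlation is undefined for constant profiles, so these must be
#' dropped before network construction. A warning reports how many were
#' removed.
#'
#' @inheritParams filter_low_expression
#' @return The filtered tibble with a `"removed_genes"` attribute.
#' @export
drop_constant_genes <- function(expr) {
  m <- expr_matrix(expr)
  v <- apply(m, 1L, stats::var)
  drop <- v == 0
  if (any(drop)) {
    warning(sprintf("Removed %d constant gene(s): %s.",
                    sum(drop),
                    paste(utils::head(expr$gene_id[drop], 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- expr[!drop, , drop = FALSE]
  attr(out, "samples") <- sample_info(expr)
  attr(out, "removed_genes") <- expr$gene_id[drop]
  out
}

#' Gene ids removed by the most recent filtering step
#' @param expr A tibble returned by [filter_low_expression()] or
#'   [drop_constant_genes()].
#' @return Character vector of removed gene ids.
#' @export
removed_genes <- function(expr) attr(expr, "removed_genes", exact = TRUE) %||% character(0)
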