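# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_coexreg <- function(msg, class = "coexreg_error", ...) {
  rlang::abort(msg, class = c(class, "coexreg_error"), ...)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_coexreg(sprintf("`%s` must be a single integer >= %d (got %s).",
                          name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort_coexreg(sprintf("`%s` must be a number in %s%g, %g%s (got %s).",
                          name, if (lo_open) "(" else "[", lo, hi,
                          if (hi_open) ")" else "]", paste(format(x), collapse = ", ")))
  }
  as.numeric(x)
}

#' Convert a tidy expression table to a genes-by-samples numeric matrix
#'
#' @param expr A data frame whose first column (`gene_id`) holds unique gene
#'   identifiers and whose remaining columns are numeric per-sample TPM values.
#' @return A numeric matrix with genes in rows (rownames = gene ids) and
#'   samples in columns.
#' @keywords internal
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"gene_id" %in% names(expr)) {
    abort_coexreg("Expression tables must have a `gene_id` first column.")
  }
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(expr)[-1][!vapply(expr[-1], is.numeric, logical(1))]
    abort_coexreg(sprintf("Non-numeric expression column(s): %s.",
                          paste(bad, collapse = ", ")))
  }
  rownames(m) <- expr$gene_id
  m
}

check_square_named <- function(x, name) {
  if (!is.matrix(x) || nrow(x) != ncol(x) || is.null(rownames(x)) ||
      !identical(rownames(x), colnames(x))) {
    abort_coexreg(sprintf(
      "`%s` must be a square matrix with identical row and column gene ids.", name))
  }
  invisible(x)
}
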