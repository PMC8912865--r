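#' GO term overrepresentation by Fisher's exact test
#'
#' For every GO term annotated to at least one module gene, tests
#' overrepresentation of the term in the module against the background with
#' the one-sided Fisher's exact test, whose p-value is the hypergeometric
#' upper tail `P(X >= k)` with `N` background genes, `K` of them annotated,
#' and a module of size `n` containing `k` annotated genes.
#'
#' @param module_genes Character vector of module gene ids (must be a subset
#'   of `background_genes`).
#' @param background_genes Character vector of background gene ids (the
#'   filtered transcript universe by default in the pipeline).
#' @param annotations Long annotation tibble (`gene_id`, `type`, `value`);
#'   only `type == "go"` rows are used.
#' @param alpha Significance threshold on the (raw) p-value; default 0.05.
#' @param adjust Apply Benjamini-Hochberg correction and flag enrichment on
#'   the adjusted p-value instead (default FALSE, matching a raw-threshold
#'   convention).
#' @return Tibble with `term`, `k`, `n`, `K`, `N`, `p_value` (and `p_adjust`
#'   when `adjust = TRUE`), `enriched`; sorted by p-value then term.
#' @export
go_enrichment <- function(module_genes, background_genes, annotations,
                          alpha = 0.05, adjust = FALSE) {
  check_annotations(annotations)
  check_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  module_genes <- unique(as.character(module_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(background_genes) < 2L) {
    abort_coexreg("The background must contain at least 2 genes.")
  }
  extra <- setdiff(module_genes, background_genes)
  if (length(extra)) {
    abort_coexreg(sprintf("Module gene(s) not in the background: %s.",
                          paste(utils::head(extra, 5), collapse = ", ")))
  }
  empty <- tibble::tibble(term = character(0), k = integer(0), n = integer(0),
                          K = integer(0), N = integer(0), p_value = numeric(0),
                          enriched = logical(0))
  if (!length(module_genes)) {
    warning("Empty module; no enrichment computed.", call. = FALSE)
    return(empty)
  }
  go <- dplyr::filter(annotations, .data$type == "go",
                      .data$gene_id %in% background_genes)
  go <- dplyr::distinct(go, .data$gene_id, .data$value)
  if (!nrow(go)) return(empty)

  N <- length(background_genes)
  n <- length(module_genes)
  counts <- go |>
    dplyr::group_by(term = .data$value) |>
    dplyr::summarise(K = dplyr::n(),
                     k = sum(.data$gene_id %in% module_genes),
                     .groups = "drop") |>
    dplyr::filter(.data$k >= 1L)
  if (!nrow(counts)) return(empty)

  out <- counts |>
    dplyr::mutate(n = n, N = N,
                  p_value = stats::phyper(.data$k - 1L, .data$K, N - .data$K,
                                          n, lower.tail = FALSE)) |>
    dplyr::select("term", "k", "n", "K", "N", "p_value")
  if (adjust) {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_adjust < alpha
  } else {
    out$enriched <- out$p_value < alpha
  }
  dplyr::arrange(out, .data$p_value, .data$term)
}

CATEGORY_TYPES <- c("cazyme_family", "cazyme_class", "tf_class",
                    "transporter_class", "ko_pathway_class", "de_status")

#' Tally functional-category membership in a gene set
#'
#' Counts module genes per category value, e.g. CAZyme families (GH18, CBM1,
#' ...), TF classes (Zn2Cys6, C2H2, ...), transporter classes, KO pathway
#' classes, or DE status. The pseudo-category `cazyme_class` aggregates
#' families into the six CAZy classes (GH, GT, CE, PL, AA, CBM) by prefix.
#'
#' @param module_genes Character vector of gene ids.
#' @param annotations Long annotation tibble (`gene_id`, `type`, `value`).
#' @param category One of `cazyme_family`, `cazyme_class`, `tf_class`,
#'   `transporter_class`, `ko_pathway_class`, `de_status`.
#' @return Tibble with `value`, `n_genes`, sorted by decreasing count then
#'   value.
#' @export
category_tally <- function(module_genes, annotations, category) {
  check_annotations(annotations)
  if (length(category) != 1L || !category %in% CATEGORY_TYPES) {
    abort_coexreg(sprintf("Unknown category `%s`; valid categories: %s.",
                          paste(category, collapse = ", "),
                          paste(CATEGORY_TYPES, collapse = ", ")))
  }
  type_needed <- if (category == "cazyme_class") "cazyme_family" else category
  ann <- annotations |>
    dplyr::filter(.data$type == type_needed,
                  .data$gene_id %in% module_genes) |>
    dplyr::distinct(.data$gene_id, .data$value)
  if (category == "cazyme_class") {
    ann$value <- cazy_class(ann$value)
  }
  ann |>
    dplyr::count(.data$value, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$value)
}

# CAZy family -> class by prefix (GH/GT/CE/PL/AA/CBM); other prefixes kept
cazy_class <- function(family) {
  m <- regmatches(family, regexpr("^(GH|GT|CE|PL|AA|CBM)", family))
  out <- family
  hit <- grepl("^(GH|GT|CE|PL|AA|CBM)", family)
  out[hit] <- m
  out
}

#' Differential-expression overlap of a gene set
#'
#' Counts module genes that are up-/down-regulated (per the supplied DE
#' status annotation) — e.g. how many cellulose-upregulated transcripts fall
#' in the cre1 group.
#'
#' @param module_genes Character vector of gene ids.
#' @param annotations Long annotation tibble with `type == "de_status"` rows
#'   whose `value` is one of `up`, `down`, `none`.
#' @return One-row tibble: `n_up`, `n_down`, `n_none`, `n_total` (module
#'   size). Warns when no module gene has DE status.
#' @export
de_overlap <- function(module_genes, annotations) {
  check_annotations(annotations)
  de <- annotations |>
    dplyr::filter(.data$type == "de_status", .data$gene_id %in% module_genes) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  if (!nrow(de) && length(module_genes)) {
    warning("No module gene has DE status; counts are zero.", call. = FALSE)
  }
  tibble::tibble(
    n_up = sum(de$value == "up"),
    n_down = sum(de$value == "down"),
    n_none = sum(de$value == "none"),
    n_total = length(unique(module_genes))
  )
}
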