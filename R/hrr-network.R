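#' Directional correlation ranks per gene
#'
#' For each gene, its neighbors are ranked 1, 2, ... by decreasing Pearson
#' correlation (ties broken by gene id; self excluded). The HRR rank of a
#' pair is the *worse* of the two directional ranks, so an edge only scores
#' well when both genes rank each other highly — the reciprocity that gives
#' the highest-reciprocal-rank network its robustness to hub domination.
#'
#' @param r Correlation matrix from [pearson_matrix()].
#' @param absolute Rank by `|r|` instead of `r` (default FALSE).
#' @return Tibble with columns `gene`, `neighbor`, `r`, `rank`
#'   (n * (n - 1) rows).
#' @export
directional_ranks <- function(r, absolute = FALSE) {
  rk <- rank_matrix(r, absolute)
  n <- nrow(r)
  genes <- rownames(r)
  out <- tibble::tibble(
    gene = rep(genes, each = n - 1L),
    neighbor = unlist(lapply(seq_len(n), function(i) genes[-i]), use.names = FALSE),
    r = unlist(lapply(seq_len(n), function(i) r[i, -i]), use.names = FALSE),
    rank = unlist(lapply(seq_len(n), function(i) rk[i, -i]), use.names = FALSE)
  )
  dplyr::arrange(out, .data$gene, .data$rank)
}

# rank_matrix[i, j] = rank of j among i's neighbors by decreasing score,
# ties by gene id; diagonal NA
rank_matrix <- function(r, absolute = FALSE) {
  check_square_named(r, "r")
  score <- if (absolute) abs(r) else r
  n <- nrow(r)
  genes <- rownames(r)
  rk <- matrix(NA_integer_, n, n, dimnames = dimnames(r))
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    ord <- js[order(-score[i, js], genes[js])]
    rk[i, ord] <- seq_along(ord)
  }
  rk
}

#' Band weight for an HRR rank
#'
#' Edges among a gene's 30 strongest reciprocal partners are coded by rank
#' band: 1/5 for ranks 1-10, 1/15 for ranks 11-20, 1/30 for ranks 21-30.
#' Ranks above 30 receive no weight (`NA`) and are excluded from the network.
#'
#' @param hrr_rank Positive integer vector of HRR ranks.
#' @return Numeric vector of band weights (NA above rank 30).
#' @export
band_weight <- function(hrr_rank) {
  if (any(is.na(hrr_rank)) || any(hrr_rank < 1) || any(hrr_rank != as.integer(hrr_rank))) {
    abort_coexreg("`hrr_rank` must be positive integers.")
  }
  dplyr::case_when(
    hrr_rank <= 10 ~ 1 / 5,
    hrr_rank <= 20 ~ 1 / 15,
    hrr_rank <= 30 ~ 1 / 30,
    TRUE ~ NA_real_
  )
}

#' Build the highest-reciprocal-rank (HRR) coexpression network
#'
#' An undirected edge (i, j) is kept iff `r_ij >= r_threshold` and the HRR
#' rank `max(rank_i(j), rank_j(i)) <= max_rank`. Kept edges carry their
#' correlation, HRR rank, and band weight (see [band_weight()]). By default
#' the correlation threshold applies to positive `r` only, so edges connect
#' coexpressed (not anti-correlated) transcripts; set `absolute = TRUE` to
#' threshold `|r|`.
#'
#' @param r Correlation matrix.
#' @param r_threshold Minimum correlation for an edge (default 0.8).
#' @param max_rank Maximum HRR rank for an edge (default 30).
#' @param absolute Apply the threshold and ranking to `|r|`.
#' @param modules Optional [cut_modules()] assignment used to label nodes.
#' @param annotations Optional long annotation tibble (`gene_id`, `type`,
#'   `value`) used to label nodes with functional categories.
#' @return An object of class `hrr_network`: list with `nodes` (tibble:
#'   `gene_id`, optional `module` and category columns), `edges` (tibble:
#'   `gene_a`, `gene_b`, `r`, `hrr_rank`, `band_weight`) and `params`.
#' @export
build_hrr_network <- function(r, r_threshold = 0.8, max_rank = 30,
                              absolute = FALSE, modules = NULL,
                              annotations = NULL) {
  check_square_named(r, "r")
  check_fraction(r_threshold, "r_threshold", lo = -1, hi = 1)
  max_rank <- check_count(max_rank, "max_rank")
  rk <- rank_matrix(r, absolute)
  score <- if (absolute) abs(r) else r
  n <- nrow(r)
  genes <- rownames(r)
  hrr <- pmax(rk, t(rk))
  keep <- !is.na(hrr) & hrr <= max_rank & score >= r_threshold &
    upper.tri(hrr)
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = genes[idx[, 1L]],
    gene_b = genes[idx[, 2L]],
    r = r[keep],
    hrr_rank = as.integer(hrr[keep]),
    band_weight = band_weight(as.integer(hrr[keep]))
  )
  edges <- dplyr::arrange(edges, .data$hrr_rank, .data$gene_a, .data$gene_b)
  nodes <- tibble::tibble(gene_id = genes)
  if (!is.null(modules)) {
    nodes <- dplyr::left_join(nodes,
                              dplyr::select(tibble::as_tibble(modules),
                                            "gene_id", "module"),
                              by = "gene_id")
  }
  if (!is.null(annotations)) {
    nodes <- dplyr::left_join(nodes, widen_annotations(annotations),
                              by = "gene_id")
  }
  new_hrr_network(nodes, edges,
                  params = list(r_threshold = r_threshold, max_rank = max_rank,
                                absolute = absolute))
}

new_hrr_network <- function(nodes, edges, params) {
  stopifnot(all(edges$gene_a != edges$gene_b))
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "hrr_network")
}

#' @export
print.hrr_network <- function(x, ...) {
  deg_nodes <- unique(c(x$edges$gene_a, x$edges$gene_b))
  cat(sprintf("<hrr_network> %d nodes (%d connected), %d edges; r >= %g, HRR rank <= %d%s\n",
              nrow(x$nodes), length(deg_nodes), nrow(x$edges),
              x$params$r_threshold, x$params$max_rank,
              if (isTRUE(x$params$absolute)) " (|r|)" else ""))
  invisible(x)
}

#' Induced subnetwork of one module
#'
#' @param net An [build_hrr_network()] result.
#' @param assignment A [cut_modules()] assignment.
#' @param label Module label to extract.
#' @return An `hrr_network` restricted to the module's genes and the edges
#'   among them.
#' @export
module_subnetwork <- function(net, assignment, label) {
  stopifnot(inherits(net, "hrr_network"))
  if (!label %in% assignment$module) {
    abort_coexreg(sprintf("Unknown module label %s.", format(label)))
  }
  keep_genes <- assignment$gene_id[assignment$module == label]
  nodes <- net$nodes[net$nodes$gene_id %in% keep_genes, , drop = FALSE]
  edges <- net$edges[net$edges$gene_a %in% keep_genes &
                       net$edges$gene_b %in% keep_genes, , drop = FALSE]
  new_hrr_network(nodes, edges, net$params)
}

#' Convert an HRR network to an igraph graph
#' @param net An `hrr_network`.
#' @return An undirected `igraph` graph with edge attributes `r`, `hrr_rank`,
#'   `band_weight` and all node metadata as vertex attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hrr_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes))
}

#' Write an HRR network for Cytoscape
#'
#' `write_hrr_edges()` emits the edge list as TSV (with node module labels
#' when present); `write_hrr_graphml()` writes GraphML via igraph, suitable
#' for import into Cytoscape.
#'
#' @param net An `hrr_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hrr_edges <- function(net, path) {
  stopifnot(inherits(net, "hrr_network"))
  edges <- net$edges
  if ("module" %in% names(net$nodes)) {
    mod <- stats::setNames(net$nodes$module, net$nodes$gene_id)
    edges$module_a <- unname(mod[edges$gene_a])
    edges$module_b <- unname(mod[edges$gene_b])
  }
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hrr_edges
#' @export
write_hrr_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

# long (gene_id, type, value) -> wide one row per gene, one column per type
widen_annotations <- function(annotations) {
  check_annotations(annotations)
  ann <- dplyr::filter(annotations, .data$type != "go")
  if (!nrow(ann)) return(tibble::tibble(gene_id = character(0)))
  ann |>
    dplyr::group_by(.data$gene_id, .data$type) |>
    dplyr::summarise(value = paste(sort(unique(.data$value)), collapse = ";"),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "value")
}

check_annotations <- function(annotations) {
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "type", "value") %in% names(annotations))) {
    abort_coexreg("Annotations must be a long table with gene_id, type, value columns.")
  }
  invisible(annotations)
}
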