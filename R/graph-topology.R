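# adjacency list (gene id -> character vector of neighbors) of an hrr_network
adjacency_list <- function(net) {
  stopifnot(inherits(net, "hrr_network"))
  genes <- net$nodes$gene_id
  adj <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) adj[[g]] <- character(0)
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$gene_a[k]; b <- net$edges$gene_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Node degrees and hub flags
#'
#' Hubs are the transcripts at the top of the degree distribution: all nodes
#' whose degree is among the `top_k` highest *distinct* degree values in the
#' graph. By convention hubs are sought within a module subnetwork (build one
#' with [module_subnetwork()]); pass the global network for global hubs.
#'
#' @param net An `hrr_network`.
#' @param top_k Number of distinct top degree values that count as hubs
#'   (default 1).
#' @return Tibble with `gene_id`, `degree`, `is_hub`, ordered by decreasing
#'   degree then gene id.
#' @export
degree_and_hubs <- function(net, top_k = 1) {
  stopifnot(inherits(net, "hrr_network"))
  top_k <- check_count(top_k, "top_k")
  if (!nrow(net$nodes)) abort_coexreg("The network has no nodes.")
  deg <- stats::setNames(rep(0L, nrow(net$nodes)), net$nodes$gene_id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$gene_a, net$edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  out <- tibble::tibble(gene_id = names(deg), degree = unname(deg))
  out <- dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene_id)
  top_vals <- utils::head(sort(unique(out$degree), decreasing = TRUE), top_k)
  out$is_hub <- out$degree %in% top_vals & out$degree > 0
  out
}

#' First neighbors of a focal transcript
#'
#' Reports every node adjacent to `node` in the HRR network, with its module
#' label, functional categories and DE status when available — the
#' composition of the direct coexpression neighborhood of a regulator such
#' as xyr1 or cre1. The number of distinct modules spanned by the
#' neighborhood is attached as `attr(, "modules_spanned")`.
#'
#' @param net An `hrr_network`.
#' @param node Focal gene id (must be a node of the network).
#' @param assignment Optional [cut_modules()] assignment for module labels.
#' @param annotations Optional long annotation tibble (`gene_id`, `type`,
#'   `value`).
#' @return Tibble of neighbors with `gene_id`, `r`, `hrr_rank`, and any
#'   module / category / `de_status` columns available.
#' @export
first_neighbors <- function(net, node, assignment = NULL, annotations = NULL) {
  stopifnot(inherits(net, "hrr_network"))
  if (!node %in% net$nodes$gene_id) {
    abort_coexreg(sprintf("Node `%s` is not in the network.", node),
                  class = "coexreg_unknown_gene")
  }
  e <- net$edges
  inc <- e$gene_a == node | e$gene_b == node
  nb <- tibble::tibble(
    gene_id = ifelse(e$gene_a[inc] == node, e$gene_b[inc], e$gene_a[inc]),
    r = e$r[inc],
    hrr_rank = e$hrr_rank[inc]
  )
  if (!is.null(assignment)) {
    nb <- dplyr::left_join(nb, dplyr::select(tibble::as_tibble(assignment),
                                             "gene_id", "module"),
                           by = "gene_id")
  } else if ("module" %in% names(net$nodes)) {
    nb <- dplyr::left_join(nb, dplyr::select(net$nodes, "gene_id", "module"),
                           by = "gene_id")
  }
  if (!is.null(annotations)) {
    nb <- dplyr::left_join(nb, widen_annotations(annotations), by = "gene_id")
  }
  nb <- dplyr::arrange(nb, .data$hrr_rank, .data$gene_id)
  attr(nb, "modules_spanned") <-
    if ("module" %in% names(nb)) dplyr::n_distinct(nb$module[!is.na(nb$module)]) else NA_integer_
  nb
}

# single-source BFS with geodesic counting:
# count(v) = sum of count(u) over neighbors u with dist(u) = dist(v) - 1
bfs_geodesics <- function(adj, source) {
  genes <- names(adj)
  dist <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  count <- stats::setNames(rep(0, length(genes)), genes)
  dist[source] <- 0L
  count[source] <- 1
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      du <- dist[[u]]
      for (v in adj[[u]]) {
        if (is.na(dist[[v]])) {
          dist[[v]] <- du + 1L
          nxt <- c(nxt, v)
          count[[v]] <- count[[u]]
        } else if (dist[[v]] == du + 1L) {
          count[[v]] <- count[[v]] + count[[u]]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, count = count)
}

#' Geodesic distances and shortest-path counts from a source transcript
#'
#' Runs a breadth-first search from `source` and, for each target, reports
#' the geodesic (shortest-path) distance, the number of distinct shortest
#' paths (by the standard predecessor-sum recurrence), and — for targets at
#' distance exactly 2 — the intermediate ("transitive") transcripts on those
#' paths.
#'
#' @param net An `hrr_network`.
#' @param source Source gene id (must be in the network).
#' @param targets Character vector of target gene ids; targets absent from
#'   the network are reported as unreachable with `note = "absent"`.
#' @return Tibble with `source`, `target`, `distance` (NA if unreachable),
#'   `n_geodesics`, `reachable`, `intermediates` (list column, non-empty only
#'   at distance 2), `note`.
#' @export
geodesics <- function(net, source, targets) {
  stopifnot(inherits(net, "hrr_network"))
  if (!source %in% net$nodes$gene_id) {
    abort_coexreg(sprintf("Source `%s` is not in the network.", source),
                  class = "coexreg_unknown_gene")
  }
  adj <- adjacency_list(net)
  bfs <- bfs_geodesics(adj, source)
  purrr::map_dfr(targets, function(tg) {
    if (!tg %in% net$nodes$gene_id) {
      return(tibble::tibble(source = source, target = tg,
                            distance = NA_integer_, n_geodesics = 0,
                            reachable = FALSE, intermediates = list(character(0)),
                            note = "absent"))
    }
    d <- bfs$dist[[tg]]
    if (is.na(d)) {
      return(tibble::tibble(source = source, target = tg,
                            distance = NA_integer_, n_geodesics = 0,
                            reachable = FALSE, intermediates = list(character(0)),
                            note = "unreachable"))
    }
    mid <- if (d == 2L) sort(intersect(adj[[source]], adj[[tg]])) else character(0)
    tibble::tibble(source = source, target = tg, distance = d,
                   n_geodesics = bfs$count[[tg]], reachable = TRUE,
                   intermediates = list(mid), note = NA_character_)
  })
}

#' Transitive transcripts on length-2 shortest paths
#'
#' When the geodesic distance between `source` and `target` is exactly 2,
#' returns every middle transcript — candidates for indirect regulation
#' between a TF and its target. For any other distance an empty tibble is
#' returned, with the actual distance in `attr(, "distance")`.
#'
#' @param net An `hrr_network`.
#' @param source,target Gene ids, both present in the network.
#' @param annotations Optional long annotation tibble for labelling middles.
#' @return Tibble of intermediate genes (possibly with annotation columns);
#'   the observed distance is in `attr(, "distance")`.
#' @export
transitive_transcripts <- function(net, source, target, annotations = NULL) {
  res <- geodesics(net, source, targets = target)
  mids <- res$intermediates[[1L]]
  out <- tibble::tibble(gene_id = mids)
  if (!is.null(annotations) && nrow(out)) {
    out <- dplyr::left_join(out, widen_annotations(annotations), by = "gene_id")
  }
  attr(out, "distance") <- res$distance[1L]
  out
}

#' Geodesic distance and count matrices between regulators and targets
#'
#' For each (regulator, target) pair — typically (xyr1, cre1) against a set
#' of CAZyme transcripts — reports the geodesic distance ("number of edges
#' that must be traversed") and the number of distinct shortest paths
#' ("number of occurrences"), in heatmap-ready long format (see
#' [plot_geodesic_heatmap()]).
#'
#' @param net An `hrr_network`.
#' @param regulators Character vector of regulator gene ids.
#' @param targets Character vector of target gene ids.
#' @return Long tibble: `regulator`, `target`, `distance`, `n_geodesics`,
#'   `reachable`, `note`.
#' @export
regulator_target_geodesics <- function(net, regulators, targets) {
  if (!length(regulators) || !length(targets)) {
    abort_coexreg("`regulators` and `targets` must be non-empty.")
  }
  purrr::map_dfr(regulators, function(reg) {
    res <- geodesics(net, reg, targets)
    tibble::tibble(regulator = reg, target = res$target,
                   distance = res$distance, n_geodesics = res$n_geodesics,
                   reachable = res$reachable, note = res$note)
  })
}
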