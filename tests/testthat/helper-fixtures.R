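# Small fixture builders shared across test files.

# hand-built HRR network from an edge list given as c("a-b", "b-c", ...)
toy_net <- function(edge_str, extra_nodes = character(0)) {
  if (length(edge_str)) {
    parts <- strsplit(edge_str, "-", fixed = TRUE)
    ga <- vapply(parts, `[`, "", 1L)
    gb <- vapply(parts, `[`, "", 2L)
  } else {
    ga <- gb <- character(0)
  }
  nodes <- sort(unique(c(ga, gb, extra_nodes)))
  structure(list(
    nodes = tibble::tibble(gene_id = nodes),
    edges = tibble::tibble(gene_a = ga, gene_b = gb,
                           r = rep(0.9, length(ga)),
                           hrr_rank = rep(1L, length(ga)),
                           band_weight = rep(0.2, length(ga))),
    params = list(r_threshold = 0.8, max_rank = 30L, absolute = FALSE)
  ), class = "hrr_network")
}

# adjacency list of a toy network, for the brute-force geodesic oracle
toy_adj <- function(net) {
  adj <- stats::setNames(lapply(net$nodes$gene_id, function(g) character(0)),
                         net$nodes$gene_id)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[k]; b <- net$edges$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# random undirected graph as a toy network
random_net <- function(n_nodes, p = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  toy_net(apply(pairs[, keep, drop = FALSE], 2, paste, collapse = "-"),
          extra_nodes = nodes)
}

# random symmetric correlation-like matrix with unit diagonal
random_cor <- function(n, genes = sprintf("g%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n, -1, 1), n, n, dimnames = list(genes, genes))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

# random adjacency-like matrix in [0, 1] with unit diagonal
random_adj <- function(n, genes = sprintf("g%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n, dimnames = list(genes, genes))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

# correlation matrix with named entries set symmetrically
cor_from_pairs <- function(genes, pairs_r, default = 0) {
  m <- matrix(default, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (p in pairs_r) {
    m[p$a, p$b] <- m[p$b, p$a] <- p$r
  }
  diag(m) <- 1
  m
}

tiny_sim <- function(noise_sd = 0, seed = 7, n_modules = 3, genes_per_module = 10,
                     n_background = 0) {
  simulate_coexpression(synthetic_design(
    n_modules = n_modules, genes_per_module = genes_per_module,
    n_background_genes = n_background,
    conditions = c(cellulose = 10L, glucose = 10L),
    noise_sd = noise_sd,
    regulator_assignments = c(xyr1 = 1L, cre1 = 2L),
    seed = seed))
}
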