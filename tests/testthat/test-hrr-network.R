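# brute-force HRR construction: directional ranks by explicit sort, then the
# double-loop reciprocity/threshold rule
brute_hrr_edges <- function(r, r_threshold = 0.8, max_rank = 30) {
  genes <- rownames(r)
  rank_of <- function(i, j) {
    others <- setdiff(genes, genes[i])
    ord <- others[order(-r[genes[i], others], others)]
    match(genes[j], ord)
  }
  out <- NULL
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      hrr <- max(rank_of(i, j), rank_of(j, i))
      if (r[i, j] >= r_threshold && hrr <= max_rank) {
        out <- rbind(out, data.frame(gene_a = genes[i], gene_b = genes[j],
                                     hrr_rank = hrr))
      }
    }
  }
  out
}

test_that("directional ranks order neighbors by decreasing r with id tie-break", {
  genes <- c("a", "b", "c", "d", "e")
  set.seed(10)
  r <- random_cor(5, genes)
  ranks <- directional_ranks(r)
  for (g in genes) {
    sub <- ranks[ranks$gene == g, ]
    others <- setdiff(genes, g)
    oracle <- others[order(-r[g, others], others)]
    expect_equal(sub$neighbor[order(sub$rank)], oracle)
  }
  # two genes rank each other 1
  r2 <- cor_from_pairs(c("x", "y"), list(list(a = "x", b = "y", r = 0.5)))
  d2 <- directional_ranks(r2)
  expect_equal(d2$rank, c(1L, 1L))
})

test_that("band weights follow the printed top-10/20/30 coding", {
  expect_equal(band_weight(5L), 1 / 5)
  expect_equal(band_weight(10L), 1 / 5)
  expect_equal(band_weight(11L), 1 / 15)
  expect_equal(band_weight(20L), 1 / 15)
  expect_equal(band_weight(21L), 1 / 30)
  expect_equal(band_weight(30L), 1 / 30)
  expect_true(is.na(band_weight(31L)))
  expect_error(band_weight(0L), "positive")
})

test_that("HRR networks equal brute-force construction on random matrices", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    r <- random_cor(n)
    # loosen the threshold so random matrices actually produce edges
    net <- build_hrr_network(r, r_threshold = 0.2, max_rank = 3)
    oracle <- brute_hrr_edges(r, r_threshold = 0.2, max_rank = 3)
    if (is.null(oracle)) {
      expect_equal(nrow(net$edges), 0L)
    } else {
      got <- net$edges[order(net$edges$gene_a, net$edges$gene_b), ]
      want <- oracle[order(oracle$gene_a, oracle$gene_b), ]
      expect_equal(got$gene_a, want$gene_a)
      expect_equal(got$gene_b, want$gene_b)
      expect_equal(got$hrr_rank, want$hrr_rank)
    }
    # structural invariants: no self loops, band coding, edge-count bound
    expect_true(all(net$edges$gene_a != net$edges$gene_b))
    expect_true(all(net$edges$band_weight %in% c(1 / 5, 1 / 15, 1 / 30)))
    expect_lte(nrow(net$edges), n * 3 / 2)
  }
})

test_that("reciprocity and the r threshold both gate edges", {
  # a-b strongly and reciprocally correlated; c correlated with many partners
  genes <- c("a", "b", "c", "d")
  r <- cor_from_pairs(genes, list(
    list(a = "a", b = "b", r = 0.95),
    list(a = "a", b = "c", r = 0.9),
    list(a = "c", b = "d", r = 0.85)))
  net <- build_hrr_network(r, r_threshold = 0.8, max_rank = 30)
  expect_true(any(net$edges$gene_a == "a" & net$edges$gene_b == "b"))
  edge_ab <- net$edges[net$edges$gene_a == "a" & net$edges$gene_b == "b", ]
  expect_equal(edge_ab$hrr_rank, 1L)
  # sub-threshold pairs never enter regardless of rank
  expect_false(any(net$edges$r < 0.8))
  # rank cap: with max_rank 1, only mutually-first pairs survive
  net1 <- build_hrr_network(r, r_threshold = 0.8, max_rank = 1)
  expect_true(all(net1$edges$hrr_rank == 1L))

  # negative correlations only count under absolute = TRUE
  rn <- cor_from_pairs(c("p", "q", "s"), list(list(a = "p", b = "q", r = -0.9)))
  expect_equal(nrow(build_hrr_network(rn)$edges), 0L)
  expect_equal(nrow(build_hrr_network(rn, absolute = TRUE)$edges), 1L)
})

test_that("module subnetworks induce the right subgraph", {
  sim <- tiny_sim(noise_sd = 0, n_modules = 2, genes_per_module = 6)
  r <- pearson_matrix(sim$expression)
  asg <- cut_modules(cluster_dendrogram(topological_overlap(
    signed_adjacency(r, 6))), min_module_size = 5)
  net <- build_hrr_network(r, modules = asg)
  grp <- regulator_group(asg, "xyr1")
  lab <- attr(grp, "module")
  sub <- module_subnetwork(net, asg, lab)
  expect_setequal(sub$nodes$gene_id, grp$gene_id)
  # zero noise: complete top-band connectivity within the module
  expect_equal(nrow(sub$edges), choose(6, 2))
  expect_true(all(sub$edges$band_weight == 1 / 5))
  expect_error(module_subnetwork(net, asg, 99), "Unknown module")
  # a label covering all nodes returns the whole network
  all_lab <- asg; all_lab$module <- 1L
  full <- module_subnetwork(net, all_lab, 1)
  expect_equal(nrow(full$edges), nrow(net$edges))
})

test_that("edge lists and GraphML export and re-import", {
  sim <- tiny_sim(noise_sd = 0, n_modules = 2, genes_per_module = 5)
  net <- build_hrr_network(pearson_matrix(sim$expression))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hrr_edges(net, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_hrr_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$gene_id)
})
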