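test_that("degrees and hubs match incidence counting", {
  star <- toy_net(c("hub-l1", "hub-l2", "hub-l3", "hub-l4"))
  deg <- degree_and_hubs(star)
  expect_equal(deg$gene_id[deg$is_hub], "hub")
  expect_equal(deg$degree[deg$gene_id == "hub"], 4L)
  expect_equal(sum(deg$degree), 2L * nrow(star$edges))

  cycle <- toy_net(c("a-b", "b-c", "c-d", "d-a"))
  dc <- degree_and_hubs(cycle)
  expect_true(all(dc$degree == 2L))
  expect_true(all(dc$is_hub))

  set.seed(20)
  for (i in 1:5) {
    net <- random_net(30)
    deg <- degree_and_hubs(net)
    oracle <- vapply(deg$gene_id, function(g) {
      sum(net$edges$gene_a == g) + sum(net$edges$gene_b == g)
    }, integer(1))
    expect_equal(deg$degree, unname(oracle))
    expect_equal(sum(deg$degree), 2L * nrow(net$edges))
  }
  # isolated nodes are never hubs
  iso <- toy_net("a-b", extra_nodes = "lonely")
  di <- degree_and_hubs(iso)
  expect_false(di$is_hub[di$gene_id == "lonely"])
})

test_that("first neighbors are the distance-1 shell with metadata attached", {
  net <- toy_net(c("xyr1-a", "xyr1-b", "a-b", "b-c"), extra_nodes = "iso")
  nb <- first_neighbors(net, "xyr1")
  expect_setequal(nb$gene_id, c("a", "b"))
  expect_equal(nrow(first_neighbors(net, "iso")), 0L)
  expect_error(first_neighbors(net, "ghost"), class = "coexreg_unknown_gene")

  asg <- coexreg:::new_module_assignment(
    c("xyr1", "a", "b", "c", "iso"), c(1L, 1L, 2L, 2L, 0L), 1L, 0.99, 2L, 0.5)
  ann <- tibble::tibble(gene_id = c("a", "b"), type = "cazyme_family",
                        value = c("GH18", "CBM1"))
  nb2 <- first_neighbors(net, "xyr1", assignment = asg, annotations = ann)
  expect_equal(attr(nb2, "modules_spanned"), 2L)
  expect_equal(nb2$cazyme_family[nb2$gene_id == "a"], "GH18")
  # neighbor shell equals the distance-1 set from the geodesic engine
  geo <- geodesics(net, "xyr1", setdiff(net$nodes$gene_id, "xyr1"))
  expect_setequal(nb$gene_id, geo$target[!is.na(geo$distance) & geo$distance == 1])
})

test_that("geodesics match hand-enumerable cases", {
  square <- toy_net(c("a-b", "b-c", "c-d", "d-a"))
  res <- geodesics(square, "a", c("a", "b", "c"))
  expect_equal(res$distance, c(0L, 1L, 2L))
  expect_equal(res$n_geodesics, c(1, 1, 2))
  expect_setequal(res$intermediates[[3]], c("b", "d"))

  # unreachable and absent targets are reported, not silently dropped
  net <- toy_net("a-b", extra_nodes = "island")
  r2 <- geodesics(net, "a", c("island", "ghost"))
  expect_equal(r2$reachable, c(FALSE, FALSE))
  expect_equal(r2$note, c("unreachable", "absent"))
  expect_equal(r2$n_geodesics, c(0, 0))
})

test_that("BFS geodesic counting equals exhaustive path enumeration on random graphs", {
  set.seed(21)
  for (i in 1:30) {
    net <- random_net(sample(4:8, 1), p = runif(1, 0.2, 0.6))
    adj <- toy_adj(net)
    nodes <- net$nodes$gene_id
    src <- sample(nodes, 1)
    res <- geodesics(net, src, nodes)
    for (row in seq_len(nrow(res))) {
      oracle <- brute_geodesics(adj, src, res$target[row])
      expect_equal(res$distance[row], oracle$distance)
      expect_equal(res$n_geodesics[row], oracle$n_geodesics)
    }
  }
})

test_that("geodesic counts agree with igraph on a larger random graph", {
  set.seed(22)
  net <- random_net(25, p = 0.15)
  g <- as_igraph(net)
  src <- net$nodes$gene_id[1]
  res <- geodesics(net, src, net$nodes$gene_id)
  for (row in seq_len(nrow(res))) {
    tg <- res$target[row]
    if (tg == src) next
    sp <- suppressWarnings(igraph::all_shortest_paths(g, from = src, to = tg))
    expect_equal(res$n_geodesics[row], length(sp$vpaths))
    if (length(sp$vpaths)) {
      expect_equal(res$distance[row], length(sp$vpaths[[1]]) - 1L)
    }
  }
})

test_that("BFS distances satisfy the triangle inequality", {
  set.seed(23)
  net <- random_net(15, p = 0.25)
  nodes <- net$nodes$gene_id
  d <- sapply(nodes, function(s) geodesics(net, s, nodes)$distance)
  dimnames(d) <- list(nodes, nodes)
  for (trial in 1:50) {
    ijk <- sample(nodes, 3)
    dij <- d[ijk[1], ijk[2]]; djk <- d[ijk[2], ijk[3]]; dik <- d[ijk[1], ijk[3]]
    if (!is.na(dij) && !is.na(djk)) {
      expect_true(is.na(dik) || dik <= dij + djk)
      if (!is.na(dik)) expect_lte(dik, dij + djk)
    }
  }
})

test_that("transitive transcripts are exactly the length-2 middles", {
  path <- toy_net(c("a-b", "b-c"))
  mid <- transitive_transcripts(path, "a", "c")
  expect_equal(mid$gene_id, "b")
  expect_equal(attr(mid, "distance"), 2L)

  adjacent <- transitive_transcripts(path, "a", "b")
  expect_equal(nrow(adjacent), 0L)
  expect_equal(attr(adjacent, "distance"), 1L)

  two_routes <- toy_net(c("s-m1", "s-m2", "m1-t", "m2-t"))
  mids <- transitive_transcripts(two_routes, "s", "t")
  expect_setequal(mids$gene_id, c("m1", "m2"))
  ann <- tibble::tibble(gene_id = "m1", type = "ko_pathway_class",
                        value = "Energy metabolism")
  mids2 <- transitive_transcripts(two_routes, "s", "t", annotations = ann)
  expect_equal(mids2$ko_pathway_class[mids2$gene_id == "m1"],
               "Energy metabolism")
})

test_that("regulator-to-target geodesic tables match per-pair recomputation", {
  set.seed(24)
  net <- random_net(20, p = 0.2)
  regs <- net$nodes$gene_id[1:2]
  targets <- net$nodes$gene_id[10:15]
  geo <- regulator_target_geodesics(net, regs, targets)
  expect_equal(nrow(geo), length(regs) * length(targets))
  for (row in seq_len(nrow(geo))) {
    single <- geodesics(net, geo$regulator[row], geo$target[row])
    expect_equal(geo$distance[row], single$distance)
    expect_equal(geo$n_geodesics[row], single$n_geodesics)
  }
  # regulator adjacent to every target: all distances and counts are 1
  star <- toy_net(c("reg-t1", "reg-t2", "reg-t3"))
  gs <- regulator_target_geodesics(star, "reg", c("t1", "t2", "t3"))
  expect_true(all(gs$distance == 1L))
  expect_true(all(gs$n_geodesics == 1))
  expect_error(regulator_target_geodesics(star, character(0), "t1"), "non-empty")
})
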