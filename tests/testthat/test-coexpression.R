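test_that("pearson_matrix matches closed-form values and rejects bad input", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(1, 2, 3), s2 = c(2, 4, 2), s3 = c(3, 6, 1),
                         s4 = c(4, 8, 4))
  # a vs b perfectly linear; a = (1,2,3,4) vs c = (3,2,1,4)? use spec-style pairs
  r <- pearson_matrix(expr)
  expect_equal(unname(r["a", "b"]), 1)
  expect_true(all(abs(r - t(r)) < 1e-12))
  expect_equal(unname(diag(r)), rep(1, 3))

  e2 <- tibble::tibble(gene_id = c("x", "y", "z"),
                       s1 = c(1, 1, 3), s2 = c(2, 3, 2), s3 = c(3, 2, 1),
                       s4 = c(4, 4, 0))
  r2 <- pearson_matrix(e2)
  expect_equal(unname(r2["x", "y"]), 0.8)   # cov 4 / (sd 5 * sd 5)
  expect_equal(unname(r2["x", "z"]), -1)

  expect_error(pearson_matrix(expr[, 1:3]), "3 samples")
  const <- tibble::tibble(gene_id = c("k"), s1 = 1, s2 = 1, s3 = 1)
  expect_error(pearson_matrix(const), "drop_constant_genes")
})

test_that("signed adjacency follows ((1 + r) / 2)^beta", {
  genes <- c("a", "b", "c")
  r <- cor_from_pairs(genes, list(list(a = "a", b = "b", r = 1),
                                  list(a = "a", b = "c", r = -1),
                                  list(a = "b", b = "c", r = 0.6)))
  a <- signed_adjacency(r, 2)
  expect_equal(unname(a["a", "b"]), 1)
  expect_equal(unname(a["a", "c"]), 0)
  expect_equal(unname(a["b", "c"]), 0.64)
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_error(signed_adjacency(r, 0), "beta")
})

test_that("TOM matches hand-computed graphs and the triple-loop oracle", {
  genes <- c("a", "b", "c")
  complete <- cor_from_pairs(genes, list(list(a = "a", b = "b", r = 1),
                                         list(a = "b", b = "c", r = 1),
                                         list(a = "a", b = "c", r = 1)))
  expect_equal(unname(topological_overlap(complete)["a", "b"]), 1)

  path <- cor_from_pairs(genes, list(list(a = "a", b = "b", r = 1),
                                     list(a = "b", b = "c", r = 1)))
  tom <- topological_overlap(path)
  expect_equal(unname(tom["a", "c"]), 0.5)     # (1 + 0) / (1 + 1 - 0)
  expect_equal(unname(tom["a", "b"]), 1)

  empty <- diag(1, 3); dimnames(empty) <- list(genes, genes)
  expect_equal(unname(topological_overlap(empty)[upper.tri(empty)]), rep(0, 3))

  set.seed(42)
  for (i in 1:5) {
    a <- random_adj(20)
    tom <- topological_overlap(a)
    expect_lt(max(abs(tom - brute_tom(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("scale-free fit equals an independent binned regression", {
  set.seed(1)
  a <- signed_adjacency(random_cor(200), 3)
  fit <- scale_free_fit(a)
  oracle <- brute_scale_free_fit(a)
  expect_equal(fit$signed_r2, oracle$signed_r2, tolerance = 1e-10)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_false(fit$degenerate)
  # uniform-degree network degenerates with signed_r2 = 0
  u <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(u) <- 1
  ufit <- scale_free_fit(u)
  expect_true(ufit$degenerate)
  expect_equal(ufit$signed_r2, 0)
})

test_that("soft-power scan: mean connectivity strictly decreasing, target honored", {
  set.seed(2)
  r <- pearson_matrix(tiny_sim(noise_sd = 0.4, n_background = 20)$expression)
  scan <- pick_soft_power(r, candidates = 1:12, r2_target = 0.8)
  expect_true(all(diff(scan$mean_k) < 0))
  ch <- chosen_power(scan)
  if (!is.na(ch)) {
    expect_equal(ch, min(scan$power[scan$signed_r2 >= 0.8 & !scan$degenerate]))
  }
  # unreachable target: full scan returned, no power chosen
  none <- pick_soft_power(r, candidates = 1:5, r2_target = 1.01)
  expect_true(is.na(chosen_power(none)))
  expect_equal(nrow(none), 5L)
})

test_that("module cut recovers clean planted blocks exactly", {
  set.seed(3)
  n_per <- 50
  genes <- sprintf("g%03d", seq_len(2 * n_per))
  block <- rep(1:2, each = n_per)
  diss <- matrix(0.9, 2 * n_per, 2 * n_per, dimnames = list(genes, genes))
  diss[outer(block, block, "==")] <- 0.1
  diss <- diss + matrix(runif(length(diss), 0, 0.01), nrow(diss)) # break ties
  diss[lower.tri(diss)] <- t(diss)[lower.tri(diss)]
  diag(diss) <- 0
  dend <- cluster_dendrogram(1 - diss)
  # top split separates the blocks
  top2 <- cutree(dend, k = 2)
  expect_equal(length(unique(top2[block == 1])), 1L)
  expect_equal(length(unique(top2[block == 2])), 1L)
  asg <- cut_modules(dend, min_module_size = 30)
  expect_equal(length(module_sizes(asg)), 2L)
  expect_equal(unname(sort(module_sizes(asg))), c(n_per, n_per))
  agreement <- table(asg$module, block)
  expect_true(all(apply(agreement, 1, function(x) min(x) == 0)))
  # labels partition the genes and sizes sum to n
  expect_equal(sum(module_sizes(asg)) + sum(asg$module == 0), length(genes))
})

test_that("degenerate cuts are handled: oversized minimum and uniform dissimilarity", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:20)
  diss <- matrix(runif(400, 0.8, 1), 20, 20, dimnames = list(genes, genes))
  diss[lower.tri(diss)] <- t(diss)[lower.tri(diss)]
  diag(diss) <- 0
  dend <- cluster_dendrogram(1 - diss)
  expect_warning(asg <- cut_modules(dend, min_module_size = 21), "unassigned")
  expect_true(all(asg$module == 0L))
})

test_that("regulator groups are located with planted truth and clear errors", {
  sim <- tiny_sim(noise_sd = 0, n_modules = 3, genes_per_module = 10)
  r <- pearson_matrix(sim$expression)
  tom <- topological_overlap(signed_adjacency(r, 6))
  asg <- cut_modules(cluster_dendrogram(tom), min_module_size = 5)
  grp <- regulator_group(asg, "xyr1")
  planted <- sim$truth$gene_id[sim$truth$module == 1]
  expect_setequal(grp$gene_id, planted)
  expect_true(grp$is_regulator[grp$gene_id == "xyr1"])

  expect_error(regulator_group(asg, "nope"), class = "coexreg_unknown_gene")
  expect_error(regulator_group(asg, "filtered_gene",
                               universe = c(asg$gene_id, "filtered_gene")),
               class = "coexreg_filtered_regulator")
})

test_that("single-gene dendrograms degrade gracefully", {
  tom <- matrix(1, 1, 1, dimnames = list("only", "only"))
  dend <- cluster_dendrogram(tom)
  asg <- cut_modules(dend, min_module_size = 1)
  expect_equal(asg$module, 1L)
})
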