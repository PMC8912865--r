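#' Pearson correlation matrix of gene expression profiles
#'
#' @param expr Expression tibble (`gene_id` + sample columns), at least 3
#'   samples, no constant genes (see [drop_constant_genes()]).
#' @return A symmetric genes-by-genes matrix of Pearson coefficients with
#'   unit diagonal, dimnames = gene ids.
#' @export
pearson_matrix <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 3L) abort_coexreg("At least 3 samples are required for correlation.")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    abort_coexreg(sprintf(
      "Constant gene(s) present (%s); run drop_constant_genes() first.",
      paste(utils::head(rownames(m)[v == 0], 5), collapse = ", ")))
  }
  r <- stats::cor(t(m))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Signed soft-threshold adjacency
#'
#' Transforms correlations with the signed map
#' `a_ij = ((1 + r_ij) / 2)^beta`, so perfectly anti-correlated genes get
#' adjacency 0 and perfectly correlated genes get 1; raising `beta`
#' suppresses weak edges and pushes the network toward scale-free topology.
#'
#' @param r Correlation matrix from [pearson_matrix()].
#' @param beta Integer soft power, >= 1.
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(r, beta) {
  check_square_named(r, "r")
  beta <- check_count(beta, "beta")
  a <- ((1 + r) / 2)^beta
  a[a > 1] <- 1
  a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Node connectivity is `k_i = sum_{j != i} a_ij`. Connectivities are binned
#' into `n_bins` equal-width bins; `log10` of the per-bin node frequency is
#' regressed on `log10` of the per-bin mean connectivity over non-empty bins.
#' The fit index is `R^2 * (-sign(slope))`, so a good power-law fit with the
#' expected decreasing degree distribution scores near +1.
#'
#' @param a Adjacency matrix.
#' @param n_bins Number of connectivity bins (default 10).
#' @return One-row tibble: `signed_r2`, `slope`, `mean_k`, `median_k`,
#'   `max_k`, `n_bins_used`, `degenerate` (TRUE when all connectivities are
#'   equal, in which case `signed_r2 = 0`).
#' @export
scale_free_fit <- function(a, n_bins = 10) {
  check_square_named(a, "a")
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  k <- rowSums(a) - diag(a)
  stats_row <- tibble::tibble(mean_k = mean(k), median_k = stats::median(k),
                              max_k = max(k))
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    return(dplyr::bind_cols(
      tibble::tibble(signed_r2 = 0, slope = NA_real_),
      stats_row, tibble::tibble(n_bins_used = 0L, degenerate = TRUE)))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0
  dk <- dk[keep]; pk <- pk[keep]
  if (length(dk) < 2L) {
    return(dplyr::bind_cols(
      tibble::tibble(signed_r2 = 0, slope = NA_real_),
      stats_row, tibble::tibble(n_bins_used = length(dk), degenerate = TRUE)))
  }
  fit <- stats::lm(log10(pk) ~ log10(dk))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  dplyr::bind_cols(
    tibble::tibble(signed_r2 = r2 * (-sign(slope)), slope = slope),
    stats_row, tibble::tibble(n_bins_used = length(dk), degenerate = FALSE))
}

#' Scan candidate soft powers for scale-free topology
#'
#' Evaluates [scale_free_fit()] for each candidate power on the signed
#' adjacency and picks the smallest power whose signed fit index reaches
#' `r2_target`. The full scan is always returned so the trade-off between
#' fit and mean connectivity can be inspected (see [autoplot.softpower_scan()]).
#'
#' @param r Correlation matrix.
#' @param candidates Ascending integer powers to evaluate (default 1:50).
#' @param r2_target Fit-index target (default 0.8).
#' @param n_bins Connectivity bins for [scale_free_fit()].
#' @return A tibble of class `softpower_scan` with one row per power and the
#'   chosen power in `attr(, "chosen_power")` (NA when no power reaches the
#'   target); also accessible via [chosen_power()].
#' @export
pick_soft_power <- function(r, candidates = 1:50, r2_target = 0.8, n_bins = 10) {
  check_square_named(r, "r")
  if (!length(candidates) || is.unsorted(candidates, strictly = TRUE)) {
    abort_coexreg("`candidates` must be a non-empty ascending integer vector.")
  }
  s <- (1 + r) / 2
  diag(s) <- 1
  scan <- purrr::map_dfr(candidates, function(b) {
    a <- s^b
    diag(a) <- 1
    dplyr::bind_cols(tibble::tibble(power = as.integer(b)), scale_free_fit(a, n_bins))
  })
  ok <- which(!scan$degenerate & scan$signed_r2 >= r2_target)
  chosen <- if (length(ok)) scan$power[min(ok)] else NA_integer_
  structure(scan, class = c("softpower_scan", class(scan)),
            chosen_power = chosen, r2_target = r2_target)
}

#' Chosen soft power of a scan
#' @param scan A [pick_soft_power()] result.
#' @return Integer power, or `NA` when no candidate met the target.
#' @export
chosen_power <- function(scan) attr(scan, "chosen_power", exact = TRUE)

#' @export
print.softpower_scan <- function(x, ...) {
  ch <- chosen_power(x)
  cat(sprintf("<softpower_scan> %d powers scanned; target signed R^2 >= %g; chosen: %s\n",
              nrow(x), attr(x, "r2_target"),
              if (is.na(ch)) "none" else ch))
  NextMethod()
}

#' Topological overlap matrix (TOM)
#'
#' For an adjacency `a`, `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' where `L_ij = sum_{u != i,j} a_iu a_uj` counts shared-neighbor support and
#' `k_i = sum_{u != i} a_iu` is node connectivity. Two genes are topologically
#' similar when they are connected *and* share neighbors. The dissimilarity
#' used for clustering is `1 - TOM`.
#'
#' @param a Adjacency matrix.
#' @return TOM matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(a) {
  check_square_named(a, "a")
  A <- a
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  # enforce exact symmetry against floating-point drift in the crossproduct
  tom <- (tom + t(tom)) / 2
  tom
}

#' Average-linkage dendrogram of TOM dissimilarity
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @return An `hclust` tree over genes (average linkage on `1 - TOM`).
#' @export
cluster_dendrogram <- function(tom) {
  check_square_named(tom, "tom")
  if (nrow(tom) == 1L) {
    # degenerate single-leaf tree
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          order = 1L, labels = rownames(tom),
                          method = "average", dist.method = "1 - TOM"),
                     class = "hclust"))
  }
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

#' Export a dendrogram as Newick text
#' @param dend An `hclust` tree.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort_coexreg("Package `ape` is required for Newick export.")
  }
  txt <- ape::write.tree(ape::as.phylo(dend))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Cut a dendrogram into modules adaptively
#'
#' Implements a gap-based adaptive variant of dynamic tree cutting: the cut
#' height is placed in the widest gap of the sorted merge-height
#' distribution, searched between a lower quantile (controlled by
#' `deep_split`; deeper splits search lower, yielding more, finer modules)
#' and the `cut_height_quantile` quantile. Among the widest candidate gaps,
#' the one whose cut yields the most branches of at least `min_module_size`
#' leaves is preferred. Branches below the cut smaller than
#' `min_module_size` are left unassigned (module 0). Modules are renumbered
#' 1, 2, ... by decreasing size (ties by smallest member gene id).
#'
#' @param dend `hclust` tree from [cluster_dendrogram()].
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height_quantile Upper bound for the cut height, as a quantile
#'   of merge heights (default 0.99).
#' @param deep_split Integer 0-3 (default 2); larger values search for the
#'   cut lower in the tree.
#' @return A tibble of class `module_assignment` with columns `gene_id`,
#'   `module` (0 = unassigned), carrying `module_sizes` and cut parameters
#'   as attributes.
#' @export
cut_modules <- function(dend, min_module_size = 30, cut_height_quantile = 0.99,
                        deep_split = 2) {
  if (!inherits(dend, "hclust")) abort_coexreg("`dend` must be an hclust tree.")
  min_module_size <- check_count(min_module_size, "min_module_size")
  check_fraction(cut_height_quantile, "cut_height_quantile", lo_open = TRUE)
  deep_split <- check_count(deep_split, "deep_split", min = 0L)
  if (deep_split > 3L) abort_coexreg("`deep_split` must be in 0..3.")
  genes <- dend$labels
  n <- length(genes)
  if (min_module_size > n) {
    warning("min_module_size exceeds the number of genes; all genes unassigned.",
            call. = FALSE)
    return(new_module_assignment(genes, rep(0L, n), min_module_size,
                                 cut_height_quantile, deep_split, NA_real_))
  }
  if (length(dend$height) == 0L) {
    return(new_module_assignment(genes, rep(1L, n), min_module_size,
                                 cut_height_quantile, deep_split, NA_real_))
  }

  h <- sort(dend$height)
  upper <- stats::quantile(h, cut_height_quantile, names = FALSE)
  # deep_split widens the gap-search window downward
  lower <- stats::quantile(h, c(0.75, 0.625, 0.5, 0.375)[deep_split + 1L],
                           names = FALSE)
  gaps <- diff(h)
  cand <- which(h[-length(h)] >= lower & gaps > 0)
  if (!length(cand)) {
    cut_h <- upper
  } else {
    cand <- utils::head(cand[order(gaps[cand], decreasing = TRUE)], 5L)
    heights_mid <- pmin((h[cand] + h[cand + 1L]) / 2, upper)
    # score each candidate cut: modules retained, then genes covered by them,
    # then gap width — guards against both fragmenting and agglomerating cuts
    score <- t(vapply(heights_mid, function(hh) {
      sizes <- table(stats::cutree(dend, h = hh))
      big <- sizes[sizes >= min_module_size]
      c(n_retained = length(big), coverage = sum(big))
    }, numeric(2)))
    ord <- order(score[, 1L], score[, 2L], gaps[cand], decreasing = TRUE)
    viable <- ord[score[ord, 1L] >= 2]
    cut_h <- if (length(viable)) heights_mid[viable[1L]] else heights_mid[ord[1L]]
  }
  raw <- stats::cutree(dend, h = cut_h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep(0L, n)
  if (length(keep)) {
    ord <- order(-as.integer(sizes[as.character(keep)]),
                 vapply(keep, function(k) min(genes[raw == k]), character(1)))
    for (i in seq_along(ord)) labels[raw == keep[ord[i]]] <- i
  }
  new_module_assignment(genes, labels, min_module_size, cut_height_quantile,
                        deep_split, cut_h)
}

new_module_assignment <- function(genes, labels, min_module_size,
                                  cut_height_quantile, deep_split, cut_height) {
  out <- tibble::tibble(gene_id = genes, module = as.integer(labels))
  sizes <- table(factor(labels[labels > 0L]))
  structure(out, class = c("module_assignment", class(out)),
            module_sizes = stats::setNames(as.integer(sizes), names(sizes)),
            min_module_size = min_module_size,
            cut_height_quantile = cut_height_quantile,
            deep_split = deep_split,
            cut_height = cut_height,
            method = "widest-gap adaptive cut")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  cat(sprintf("<module_assignment> %d genes; %d modules (sizes %s); %d unassigned; cut height %.4g\n",
              nrow(x), length(sizes),
              paste(utils::head(sizes, 8), collapse = ", "),
              sum(x$module == 0L), attr(x, "cut_height")))
  NextMethod()
}

#' Module sizes of an assignment
#' @param assignment A [cut_modules()] result.
#' @return Named integer vector, label -> size (label 0 excluded).
#' @export
module_sizes <- function(assignment) attr(assignment, "module_sizes", exact = TRUE)

#' The module containing a designated regulator transcript
#'
#' Identifies the module of a regulator gene (e.g. `xyr1` or `cre1`) and
#' returns all its co-members — the "regulator group" whose composition,
#' enrichment and topology the downstream analyses characterize.
#'
#' @param assignment A [cut_modules()] result.
#' @param regulator_gene Gene id of the regulator.
#' @param universe Optional character vector of all gene ids present before
#'   filtering, used to distinguish "filtered out" from "unknown id" in the
#'   error message.
#' @return Tibble of member genes (`gene_id`, `module`, `is_regulator`) with
#'   the module label in `attr(, "module")`. If the regulator is unassigned
#'   (module 0) the unassigned set is returned with a warning.
#' @export
regulator_group <- function(assignment, regulator_gene, universe = NULL) {
  if (!inherits(assignment, "module_assignment")) {
    abort_coexreg("`assignment` must come from cut_modules().")
  }
  idx <- match(regulator_gene, assignment$gene_id)
  if (is.na(idx)) {
    if (!is.null(universe) && regulator_gene %in% universe) {
      abort_coexreg(sprintf(
        "Regulator `%s` was filtered out before module detection.", regulator_gene),
        class = "coexreg_filtered_regulator")
    }
    abort_coexreg(sprintf("Unknown gene id `%s`.", regulator_gene),
                  class = "coexreg_unknown_gene")
  }
  lab <- assignment$module[idx]
  if (lab == 0L) {
    warning(sprintf("Regulator `%s` is unassigned (module 0).", regulator_gene),
            call. = FALSE)
  }
  members <- assignment[assignment$module == lab, , drop = FALSE]
  out <- tibble::tibble(gene_id = members$gene_id, module = members$module,
                        is_regulator = members$gene_id == regulator_gene)
  attr(out, "module") <- lab
  out
}
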