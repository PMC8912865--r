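#' Describe a synthetic coexpression study design
#'
#' A design plants `n_modules` blocks of coexpressed genes on top of a
#' background of independent genes, under a two-condition replicated layout
#' mimicking a carbon-source contrast (e.g. cellulose vs glucose). Each
#' planted module has a latent per-sample eigenprofile; member genes are
#' noisy scaled copies of it. Designated regulator transcripts (such as
#' `xyr1` and `cre1`) are planted as ordinary members of chosen modules so
#' that regulator-centric analyses have a ground truth.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per planted module (regulators count toward
#'   their module's size).
#' @param n_background_genes Number of independent background genes.
#' @param conditions Named integer vector: condition label -> replicate count.
#'   The total sample count is the sum of replicate counts.
#' @param noise_sd Standard deviation of the per-gene Gaussian noise added on
#'   top of the module eigenprofile (0 = perfectly correlated modules).
#' @param loading_range Length-2 numeric in (0, 1]: per-gene loadings on the
#'   module eigenprofile are drawn uniformly from this interval.
#' @param condition_effect Numeric, recycled to `n_modules`: an offset added
#'   to the module eigenprofile in samples of the *first* condition, so that
#'   condition-specific (DE-like) modules can be planted. Default 0.
#' @param regulator_assignments Named integer vector mapping regulator gene
#'   names to the planted module (1-based) each belongs to.
#' @param tpm_mean Target mean of the TPM-like rescaling applied per gene.
#' @param seed Integer seed; generation is fully deterministic given the
#'   design.
#' @return A validated list of class `synthetic_design`.
#' @seealso [simulate_coexpression()]
#' @export
synthetic_design <- function(n_modules = 5,
                             genes_per_module = 100,
                             n_background_genes = 100,
                             conditions = c(cellulose = 10L, glucose = 10L),
                             noise_sd = 0.3,
                             loading_range = c(0.5, 1),
                             condition_effect = 0,
                             regulator_assignments = c(xyr1 = 1L, cre1 = 2L),
                             tpm_mean = 10,
                             seed = 1L) {
  n_modules <- check_count(n_modules, "n_modules")
  genes_per_module <- check_count(genes_per_module, "genes_per_module", min = 2L)
  n_background_genes <- check_count(n_background_genes, "n_background_genes", min = 0L)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    abort_coexreg("`conditions` must be a named vector of replicate counts.")
  }
  conditions <- vapply(seq_along(conditions), function(i) {
    check_count(conditions[[i]], sprintf("conditions[%s]", names(conditions)[i]))
  }, integer(1)) |> stats::setNames(names(conditions))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0) {
    abort_coexreg("`noise_sd` must be a single non-negative number.")
  }
  if (length(loading_range) != 2L || any(loading_range <= 0) ||
      any(loading_range > 1) || loading_range[1] > loading_range[2]) {
    abort_coexreg("`loading_range` must be an increasing interval within (0, 1].")
  }
  condition_effect <- rep_len(as.numeric(condition_effect), n_modules)
  if (length(regulator_assignments)) {
    if (is.null(names(regulator_assignments)) || anyDuplicated(names(regulator_assignments))) {
      abort_coexreg("`regulator_assignments` must have unique regulator names.")
    }
    bad <- regulator_assignments < 1 | regulator_assignments > n_modules
    if (any(bad)) {
      abort_coexreg(sprintf(
        "Regulator(s) %s assigned to module indices outside 1..%d.",
        paste(names(regulator_assignments)[bad], collapse = ", "), n_modules))
    }
    if (length(regulator_assignments) > 0 &&
        max(table(regulator_assignments)) > genes_per_module) {
      abort_coexreg("More regulators assigned to a module than `genes_per_module`.")
    }
  }
  structure(list(
    n_modules = n_modules,
    genes_per_module = genes_per_module,
    n_background_genes = n_background_genes,
    conditions = conditions,
    n_samples = sum(conditions),
    noise_sd = as.numeric(noise_sd),
    loading_range = as.numeric(loading_range),
    condition_effect = condition_effect,
    regulator_assignments = as.integer(regulator_assignments) |>
      stats::setNames(names(regulator_assignments)),
    tpm_mean = as.numeric(tpm_mean),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design> %d modules x %d genes + %d background; %d samples (%s); noise_sd %g; seed %d\n",
    x$n_modules, x$genes_per_module, x$n_background_genes, x$n_samples,
    paste(sprintf("%s x%d", names(x$conditions), x$conditions), collapse = ", "),
    x$noise_sd, x$seed))
  if (length(x$regulator_assignments)) {
    cat("  regulators:",
        paste(sprintf("%s -> module %d", names(x$regulator_assignments),
                      x$regulator_assignments), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a TPM expression table with planted coexpression modules
#'
#' Generates `genes_per_module` genes per module as
#' `loading_g * eigenprofile_m + Normal(0, noise_sd)` per sample, plus
#' independent Gaussian background genes, then shifts each gene to a minimum
#' of zero and rescales it to a TPM-like mean. The shift/scale is affine and
#' positive per gene, so all pairwise Pearson correlations — and therefore
#' everything downstream — are unchanged by it. With `noise_sd = 0` every
#' within-module gene pair is perfectly correlated and cross-module pairs
#' inherit the correlation of their eigenprofiles.
#'
#' @param design A [synthetic_design()].
#' @return A list of class `coex_sim` with elements
#'   * `expression`: tibble, `gene_id` plus one numeric column per sample;
#'   * `samples`: tibble with `sample`, `condition`, `replicate`;
#'   * `truth`: tibble with `gene_id`, `module` (0 = background),
#'     `is_regulator`, `loading`;
#'   * `eigenprofiles`: tibble with `module` and one column per sample.
#' @examples
#' sim <- simulate_coexpression(synthetic_design(
#'   n_modules = 2, genes_per_module = 5, n_background_genes = 0,
#'   conditions = c(cellulose = 3, glucose = 3), noise_sd = 0, seed = 1))
#' sim$truth
#' @export
simulate_coexpression <- function(design) {
  if (!inherits(design, "synthetic_design")) {
    abort_coexreg("`design` must be created with synthetic_design().")
  }
  set.seed(design$seed)
  n_mod_genes <- design$n_modules * design$genes_per_module
  n_genes <- n_mod_genes + design$n_background_genes
  sample_ids <- unlist(lapply(names(design$conditions), function(cn) {
    sprintf("%s_rep%d", cn, seq_len(design$conditions[[cn]]))
  }), use.names = FALSE)
  samples <- tibble::tibble(
    sample = sample_ids,
    condition = rep(names(design$conditions), design$conditions),
    replicate = unlist(lapply(design$conditions, seq_len), use.names = FALSE)
  )
  first_cond <- samples$condition == names(design$conditions)[1]

  # gene ids: module genes first, regulators substituted into their modules
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  module_of <- c(rep(seq_len(design$n_modules), each = design$genes_per_module),
                 rep(0L, design$n_background_genes))
  is_reg <- rep(FALSE, n_genes)
  if (length(design$regulator_assignments)) {
    used <- integer(0)
    for (i in seq_along(design$regulator_assignments)) {
      m <- design$regulator_assignments[[i]]
      slot <- max(setdiff(which(module_of == m), used))
      gene_ids[slot] <- names(design$regulator_assignments)[i]
      is_reg[slot] <- TRUE
      used <- c(used, slot)
    }
  }

  eig <- matrix(stats::rnorm(design$n_modules * design$n_samples),
                nrow = design$n_modules)
  eig[, first_cond] <- eig[, first_cond] + design$condition_effect
  loading <- stats::runif(n_genes, design$loading_range[1], design$loading_range[2])
  loading[module_of == 0L] <- NA_real_

  x <- matrix(0, nrow = n_genes, ncol = design$n_samples,
              dimnames = list(gene_ids, sample_ids))
  for (g in seq_len(n_genes)) {
    base <- if (module_of[g] > 0L) loading[g] * eig[module_of[g], ] else stats::rnorm(design$n_samples)
    noise <- if (design$noise_sd > 0) stats::rnorm(design$n_samples, 0, design$noise_sd) else 0
    x[g, ] <- base + noise
  }
  # TPM-like affine rescale per gene: min 0, target mean (correlation-invariant)
  x <- x - apply(x, 1L, min)
  mu <- rowMeans(x)
  scale_to <- ifelse(mu > 0, design$tpm_mean / mu, 1)
  x <- x * scale_to

  structure(list(
    expression = dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                                  tibble::as_tibble(x)),
    samples = samples,
    truth = tibble::tibble(gene_id = gene_ids, module = module_of,
                           is_regulator = is_reg, loading = loading),
    eigenprofiles = dplyr::bind_cols(
      tibble::tibble(module = seq_len(design$n_modules)),
      tibble::as_tibble(eig, .name_repair = ~sample_ids)),
    design = design
  ), class = "coex_sim")
}

#' @export
print.coex_sim <- function(x, ...) {
  cat(sprintf("<coex_sim> %d genes x %d samples; %d planted modules, %d background genes\n",
              nrow(x$expression), nrow(x$samples), x$design$n_modules,
              x$design$n_background_genes))
  invisible(x)
}

#' Simulate annotation tables with planted GO enrichment and category labels
#'
#' Each planted module receives `terms_per_module` dedicated GO-like terms,
#' annotated to a fraction `enrichment_fraction` of its member genes plus a
#' `background_rate` fraction of all other genes, so Fisher overrepresentation
#' has a known signal. A subset of genes also receives CAZyme-family,
#' TF-class, transporter-class and KO pathway-class labels, and a per-module
#' differential-expression status can be planted for DE-overlap tallies.
#'
#' @param truth The `truth` tibble of a [simulate_coexpression()] result
#'   (columns `gene_id`, `module`).
#' @param terms_per_module Dedicated GO-like terms per planted module
#'   (0 = no GO annotation at all).
#' @param enrichment_fraction Fraction in (0, 1] of module genes annotated
#'   with each dedicated term.
#' @param background_rate Fraction in \[0, 1\] of non-module genes annotated
#'   with each dedicated term (0 = perfectly module-specific terms).
#' @param cazyme_fraction,tf_fraction,transporter_fraction,ko_fraction
#'   Fractions of all genes receiving each category label type.
#' @param up_modules,down_modules Planted-module indices whose genes are
#'   marked `up` / `down`; all other genes are `none`.
#' @param seed Integer seed.
#' @return A long tibble with columns `gene_id`, `type`, `value`, where
#'   `type` is one of `go`, `cazyme_family`, `tf_class`, `transporter_class`,
#'   `ko_pathway_class`, `de_status`.
#' @export
simulate_annotations <- function(truth,
                                 terms_per_module = 5,
                                 enrichment_fraction = 0.8,
                                 background_rate = 0.05,
                                 cazyme_fraction = 0.08,
                                 tf_fraction = 0.03,
                                 transporter_fraction = 0.05,
                                 ko_fraction = 0.3,
                                 up_modules = integer(0),
                                 down_modules = integer(0),
                                 seed = 1L) {
  if (!is.data.frame(truth) || nrow(truth) == 0 ||
      !all(c("gene_id", "module") %in% names(truth))) {
    abort_coexreg("`truth` must be a non-empty data frame with gene_id and module columns.")
  }
  terms_per_module <- check_count(terms_per_module, "terms_per_module", min = 0L)
  check_fraction(enrichment_fraction, "enrichment_fraction", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(background_rate, "background_rate")
  set.seed(check_count(seed, "seed", min = 0L))

  genes <- truth$gene_id
  modules <- sort(unique(truth$module[truth$module > 0L]))
  rows <- list()

  term_counter <- 0L
  for (m in modules) {
    members <- genes[truth$module == m]
    others <- setdiff(genes, members)
    for (t in seq_len(terms_per_module)) {
      term_counter <- term_counter + 1L
      term <- sprintf("GO:%07d", term_counter)
      n_in <- max(1L, round(enrichment_fraction * length(members)))
      annotated <- sample(members, n_in)
      if (background_rate > 0 && length(others)) {
        n_bg <- round(background_rate * length(others))
        if (n_bg > 0) annotated <- c(annotated, sample(others, n_bg))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = annotated, type = "go", value = term)
    }
  }

  pick <- function(frac) {
    n <- round(frac * length(genes))
    if (n > 0) sample(genes, n) else character(0)
  }
  cazyme_vocab <- c("GH1", "GH3", "GH5", "GH6", "GH7", "GH10", "GH16", "GH18",
                    "GH45", "GH55", "GT2", "GT90", "CE5", "PL1", "AA9", "CBM1")
  tf_vocab <- c("Zn2Cys6", "C2H2", "bZIP", "bHLH")
  transporter_vocab <- c("MFS", "ABC", "AAAP")
  ko_vocab <- c("Carbohydrate metabolism", "Energy metabolism",
                "Amino acid metabolism", "Translation",
                "Transport and catabolism", "Signal transduction")
  cat_rows <- function(type, vocab, frac) {
    g <- pick(frac)
    if (!length(g)) return(NULL)
    tibble::tibble(gene_id = g, type = type,
                   value = sample(vocab, length(g), replace = TRUE))
  }
  rows <- c(rows, list(
    cat_rows("cazyme_family", cazyme_vocab, cazyme_fraction),
    cat_rows("tf_class", tf_vocab, tf_fraction),
    cat_rows("transporter_class", transporter_vocab, transporter_fraction),
    cat_rows("ko_pathway_class", ko_vocab, ko_fraction)
  ))

  de <- rep("none", length(genes))
  de[truth$module %in% up_modules] <- "up"
  de[truth$module %in% down_modules] <- "down"
  rows[[length(rows) + 1L]] <- tibble::tibble(gene_id = genes, type = "de_status",
                                              value = de)

  out <- dplyr::bind_rows(rows)
  dplyr::arrange(dplyr::distinct(out), .data$type, .data$value, .data$gene_id)
}
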