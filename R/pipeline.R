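#' Configure an end-to-end coexpression pipeline run
#'
#' Collects every tunable of the pipeline — input paths, the low-expression
#' filter threshold, the soft-power grid and fit target, module-cut
#' parameters, HRR thresholds, regulator ids, enrichment alpha — into a
#' validated config object consumed by [run_pipeline()]. A config can also be
#' read from a YAML or JSON file with [read_config()].
#'
#' @param expression_path,metadata_path Input expression and sample-metadata
#'   tables (see [read_expression()]).
#' @param annotation_path Optional long annotation TSV (`gene_id`, `type`,
#'   `value`); required when enrichment or category tallies are wanted.
#' @param regulators Character vector of regulator gene ids (e.g.
#'   `c("xyr1", "cre1")`).
#' @param cazyme_targets Optional character vector of target gene ids for the
#'   geodesic analysis; when `NULL` and annotations carry `cazyme_family`
#'   rows, all CAZyme-annotated genes in the network are used.
#' @param max_zero_fraction Low-expression filter threshold (see
#'   [filter_low_expression()]).
#' @param powers,r2_target,n_bins Soft-power scan settings (see
#'   [pick_soft_power()]).
#' @param fallback_power Power used if no candidate reaches `r2_target`
#'   (default: the scanned power with the best fit).
#' @param min_module_size,cut_height_quantile,deep_split Module-cut settings
#'   (see [cut_modules()]).
#' @param r_threshold,max_rank HRR network settings (see
#'   [build_hrr_network()]).
#' @param alpha Enrichment significance threshold.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param out_dir Output directory (created if needed).
#' @return A list of class `coex_config`.
#' @export
coex_config <- function(expression_path,
                        metadata_path,
                        annotation_path = NULL,
                        regulators = character(0),
                        cazyme_targets = NULL,
                        max_zero_fraction = 0.5,
                        powers = 1:50,
                        r2_target = 0.8,
                        n_bins = 10,
                        fallback_power = NULL,
                        min_module_size = 30,
                        cut_height_quantile = 0.99,
                        deep_split = 2,
                        r_threshold = 0.8,
                        max_rank = 30,
                        alpha = 0.05,
                        seed = 1L,
                        out_dir = "coexreg_run") {
  cfg <- list(
    expression_path = expression_path, metadata_path = metadata_path,
    annotation_path = annotation_path, regulators = as.character(regulators),
    cazyme_targets = cazyme_targets,
    max_zero_fraction = check_fraction(max_zero_fraction, "max_zero_fraction"),
    powers = as.integer(powers), r2_target = as.numeric(r2_target),
    n_bins = check_count(n_bins, "n_bins", min = 2L),
    fallback_power = fallback_power,
    min_module_size = check_count(min_module_size, "min_module_size"),
    cut_height_quantile = check_fraction(cut_height_quantile,
                                         "cut_height_quantile", lo_open = TRUE),
    deep_split = check_count(deep_split, "deep_split", min = 0L),
    r_threshold = check_fraction(r_threshold, "r_threshold", lo = -1),
    max_rank = check_count(max_rank, "max_rank"),
    alpha = check_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE),
    seed = check_count(seed, "seed", min = 0L),
    out_dir = out_dir
  )
  structure(cfg, class = "coex_config")
}

#' Read a pipeline config from YAML or JSON
#' @param path Config file (`.yaml`/`.yml` or `.json`) whose keys match the
#'   arguments of [coex_config()].
#' @return A `coex_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_coexreg(sprintf("Config file not found: %s", path))
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_coexreg("Package `yaml` is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(coex_config, vals)
}

#' Run the full regulator-centric coexpression pipeline
#'
#' Executes, in order: low-expression filter (+ constant-gene removal),
#' Pearson correlation, soft-power scan, signed adjacency and TOM, module
#' detection, regulator-group identification, HRR network construction,
#' topology (hubs per regulator group, first neighbors, regulator-to-target
#' geodesics), and GO enrichment of the regulator groups. Every stage writes
#' a TSV under `out_dir`, and a JSON manifest records parameters, the seed,
#' and an MD5 checksum per output so that identical configs are verifiably
#' reproducible. Any missing input path aborts before any computation.
#'
#' @param config A [coex_config()].
#' @return The manifest (list, class `coex_manifest`), invisibly; it is also
#'   written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "coex_config")) {
    abort_coexreg("`config` must be created with coex_config() or read_config().")
  }
  # pre-flight: every referenced input must exist before any computation
  for (p in c(config$expression_path, config$metadata_path, config$annotation_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort_coexreg(sprintf("Input file not found: %s", p),
                    class = "coexreg_preflight_error")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  out <- function(name) file.path(config$out_dir, name)
  add_stage <- function(stages, name, files, info = list()) {
    # record basenames so manifests are independent of out_dir placement
    stages[[name]] <- c(list(outputs = as.list(basename(files)),
                             md5 = as.list(unname(tools::md5sum(files)))), info)
    stages
  }

  # 1. filter
  expr <- read_expression(config$expression_path, config$metadata_path)
  samples <- sample_info(expr)
  expr_f <- filter_low_expression(expr, samples, config$max_zero_fraction)
  removed_low <- removed_genes(expr_f)
  expr_f <- suppressWarnings(drop_constant_genes(expr_f))
  removed_const <- removed_genes(expr_f)
  readr::write_tsv(expr_f, out("expression_filtered.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(
    gene_id = c(removed_low, removed_const),
    reason = c(rep("low_expression", length(removed_low)),
               rep("constant", length(removed_const)))),
    out("genes_removed.tsv"), progress = FALSE)
  stages <- add_stage(stages, "filter",
                      c(out("expression_filtered.tsv"), out("genes_removed.tsv")),
                      list(n_genes_kept = nrow(expr_f),
                           n_genes_removed = length(removed_low) + length(removed_const)))

  # 2. correlation
  r <- pearson_matrix(expr_f)
  # the dense correlation matrix is not persisted; derived tables are
  stages[["correlation"]] <- list(outputs = list(), md5 = list(),
                                  n_genes = nrow(r), n_samples = ncol(expr_f) - 1L)

  # 3. soft power
  scan <- pick_soft_power(r, config$powers, config$r2_target, config$n_bins)
  readr::write_tsv(tidy(scan), out("softpower_scan.tsv"), progress = FALSE)
  power <- chosen_power(scan)
  if (is.na(power)) {
    power <- config$fallback_power %||% scan$power[which.max(scan$signed_r2)]
    message(sprintf("No power reached signed R^2 >= %g; using fallback power %d.",
                    config$r2_target, power))
  }
  stages <- add_stage(stages, "soft_power", out("softpower_scan.tsv"),
                      list(chosen_power = power,
                           reached_target = !is.na(chosen_power(scan))))

  # 4. adjacency + TOM
  adj <- signed_adjacency(r, power)
  tom <- topological_overlap(adj)
  stages[["tom"]] <- list(outputs = list(), md5 = list(),
                          power = power, tom_range = range(tom))

  # 5. modules
  dend <- cluster_dendrogram(tom)
  assign <- cut_modules(dend, config$min_module_size,
                        config$cut_height_quantile, config$deep_split)
  mod_tbl <- tidy(assign)
  mod_tbl$is_regulator <- mod_tbl$gene_id %in% config$regulators
  readr::write_tsv(mod_tbl, out("modules.tsv"), progress = FALSE)
  stages <- add_stage(stages, "modules", out("modules.tsv"),
                      list(n_modules = length(module_sizes(assign)),
                           n_unassigned = sum(assign$module == 0L)))

  # 6. regulator groups
  groups <- list()
  for (reg in config$regulators) {
    grp <- tryCatch(
      suppressWarnings(regulator_group(assign, reg, universe = expr$gene_id)),
      coexreg_error = function(e) NULL)
    if (!is.null(grp)) groups[[reg]] <- grp
  }
  grp_tbl <- if (length(groups)) {
    dplyr::bind_rows(lapply(names(groups), function(reg) {
      dplyr::mutate(groups[[reg]], regulator = reg)
    }))
  } else {
    tibble::tibble(gene_id = character(0), module = integer(0),
                   is_regulator = logical(0), regulator = character(0))
  }
  readr::write_tsv(grp_tbl, out("regulator_groups.tsv"), progress = FALSE)
  stages <- add_stage(stages, "regulator_groups", out("regulator_groups.tsv"),
                      list(regulators_found = names(groups)))

  # 7. HRR network
  annotations <- if (!is.null(config$annotation_path)) {
    readr::read_tsv(config$annotation_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  net <- build_hrr_network(r, config$r_threshold, config$max_rank,
                           modules = assign, annotations = annotations)
  write_hrr_edges(net, out("hrr_edges.tsv"))
  write_hrr_graphml(net, out("hrr_network.graphml"))
  stages <- add_stage(stages, "hrr",
                      c(out("hrr_edges.tsv"), out("hrr_network.graphml")),
                      list(n_edges = nrow(net$edges)))

  # 8. topology: per-group hubs, first neighbors, geodesics to targets
  hub_tbl <- dplyr::bind_rows(lapply(names(groups), function(reg) {
    lab <- attr(groups[[reg]], "module")
    if (lab == 0L) return(NULL)
    sub <- module_subnetwork(net, assign, lab)
    dplyr::mutate(degree_and_hubs(sub), regulator = reg, module = lab)
  }))
  readr::write_tsv(hub_tbl, out("hubs.tsv"), progress = FALSE)
  nb_tbl <- dplyr::bind_rows(lapply(names(groups), function(reg) {
    if (!reg %in% net$nodes$gene_id) return(NULL)
    dplyr::mutate(first_neighbors(net, reg, assign, annotations),
                  regulator = reg)
  }))
  readr::write_tsv(nb_tbl, out("first_neighbors.tsv"), progress = FALSE)
  targets <- config$cazyme_targets
  if (is.null(targets) && !is.null(annotations)) {
    targets <- intersect(
      unique(annotations$gene_id[annotations$type == "cazyme_family"]),
      net$nodes$gene_id)
  }
  topo_files <- c(out("hubs.tsv"), out("first_neighbors.tsv"))
  if (length(targets) && length(names(groups))) {
    geo <- regulator_target_geodesics(net, intersect(names(groups),
                                                     net$nodes$gene_id), targets)
    readr::write_tsv(dplyr::select(geo, -dplyr::any_of("intermediates")),
                     out("geodesics.tsv"), progress = FALSE)
    topo_files <- c(topo_files, out("geodesics.tsv"))
  }
  stages <- add_stage(stages, "topology", topo_files,
                      list(n_targets = length(targets)))

  # 9. enrichment of the regulator groups
  enr_files <- character(0)
  if (!is.null(annotations) && length(groups)) {
    enr_tbl <- dplyr::bind_rows(lapply(names(groups), function(reg) {
      res <- suppressWarnings(
        go_enrichment(groups[[reg]]$gene_id, expr_f$gene_id, annotations,
                      alpha = config$alpha))
      if (nrow(res)) dplyr::mutate(res, regulator = reg) else NULL
    }))
    readr::write_tsv(enr_tbl, out("go_enrichment.tsv"), progress = FALSE)
    tally_tbl <- dplyr::bind_rows(lapply(names(groups), function(reg) {
      dplyr::bind_rows(lapply(intersect(CATEGORY_TYPES, c("cazyme_family",
                                                          "cazyme_class", "tf_class",
                                                          "transporter_class",
                                                          "ko_pathway_class")),
                              function(cat) {
        t <- category_tally(groups[[reg]]$gene_id, annotations, cat)
        if (nrow(t)) dplyr::mutate(t, category = cat, regulator = reg) else NULL
      }))
    }))
    readr::write_tsv(tally_tbl, out("category_tallies.tsv"), progress = FALSE)
    de_tbl <- dplyr::bind_rows(lapply(names(groups), function(reg) {
      dplyr::mutate(suppressWarnings(de_overlap(groups[[reg]]$gene_id, annotations)),
                    regulator = reg)
    }))
    readr::write_tsv(de_tbl, out("de_overlap.tsv"), progress = FALSE)
    enr_files <- c(out("go_enrichment.tsv"), out("category_tallies.tsv"),
                   out("de_overlap.tsv"))
  }
  stages <- if (length(enr_files)) {
    add_stage(stages, "enrichment", enr_files)
  } else {
    stages[["enrichment"]] <- list(outputs = list(), md5 = list(),
                                   skipped = "no annotations or no regulator groups")
    stages
  }

  manifest <- list(
    package = "coexreg",
    version = as.character(utils::packageVersion("coexreg")),
    seed = config$seed,
    parameters = unclass(config),
    module_cut_method = attr(assign, "method"),
    geodesic_interpretation = paste(
      "distance = geodesic length (minimal number of edges);",
      "n_geodesics = number of distinct shortest paths"),
    stages = stages
  )
  manifest$parameters$out_dir <- NULL # keep manifests path-independent
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, out("manifest.json"))
  invisible(structure(manifest, class = "coex_manifest"))
}

#' @export
print.coex_manifest <- function(x, ...) {
  cat(sprintf("<coex_manifest> coexreg %s; seed %d; %d stages: %s\n",
              x$version, x$seed, length(x$stages),
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Simulates a dataset from a [synthetic_design()] and writes the expression
#' table, sample metadata, annotations and planted truth as TSVs in the
#' exact dialects the pipeline reads back.
#'
#' @param design A [synthetic_design()].
#' @param dir Output directory (created if needed).
#' @param ... Passed to [simulate_annotations()] (e.g. `terms_per_module`).
#' @return Named list of written file paths, invisibly.
#' @export
simulate_to_dir <- function(design, dir, ...) {
  sim <- simulate_coexpression(design)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$expression, paths$expression, progress = FALSE)
  readr::write_tsv(sim$samples, paths$samples, progress = FALSE)
  ann <- simulate_annotations(sim$truth, seed = design$seed, ...)
  readr::write_tsv(ann, paths$annotations, progress = FALSE)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
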