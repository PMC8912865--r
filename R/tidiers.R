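#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a soft-power scan
#' @param x A [pick_soft_power()] result.
#' @param ... Unused.
#' @return The scan as a plain tibble (one row per candidate power).
#' @method tidy softpower_scan
#' @export
tidy.softpower_scan <- function(x, ...) {
  tibble::as_tibble(unclass_scan(x))
}

#' @rdname tidy.softpower_scan
#' @method glance softpower_scan
#' @export
glance.softpower_scan <- function(x, ...) {
  ch <- chosen_power(x)
  row <- if (!is.na(ch)) x[x$power == ch, ] else x[which.max(x$signed_r2), ]
  tibble::tibble(chosen_power = ch, r2_target = attr(x, "r2_target"),
                 signed_r2 = row$signed_r2, mean_k = row$mean_k,
                 n_candidates = nrow(x))
}

unclass_scan <- function(x) {
  attr(x, "chosen_power") <- NULL
  attr(x, "r2_target") <- NULL
  class(x) <- setdiff(class(x), "softpower_scan")
  x
}

#' Tidy a module assignment
#' @param x A [cut_modules()] result.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `module`.
#' @method tidy module_assignment
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, module = x$module)
}

#' @rdname tidy.module_assignment
#' @method glance module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  sizes <- module_sizes(x)
  tibble::tibble(
    n_genes = nrow(x),
    n_modules = length(sizes),
    n_unassigned = sum(x$module == 0L),
    largest_module = if (length(sizes)) max(sizes) else NA_integer_,
    min_module_size = attr(x, "min_module_size"),
    cut_height = attr(x, "cut_height")
  )
}

#' Tidy an HRR network
#' @param x A [build_hrr_network()] result.
#' @param ... Unused.
#' @return The edge tibble (`gene_a`, `gene_b`, `r`, `hrr_rank`,
#'   `band_weight`).
#' @method tidy hrr_network
#' @export
tidy.hrr_network <- function(x, ...) x$edges

#' @rdname tidy.hrr_network
#' @method glance hrr_network
#' @export
glance.hrr_network <- function(x, ...) {
  connected <- unique(c(x$edges$gene_a, x$edges$gene_b))
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_connected = length(connected),
    n_edges = nrow(x$edges),
    r_threshold = x$params$r_threshold,
    max_rank = x$params$max_rank
  )
}
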