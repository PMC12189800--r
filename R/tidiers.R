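# broom-style tidiers for the package's fitted objects.

#' Tidy a Louvain result
#'
#' @param x A `louvain_result`.
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `community`.
#' @export
tidy.louvain_result <- function(x, ...) {
  x$membership
}

#' One-row summary of a Louvain result
#'
#' @param x A `louvain_result`.
#' @param ... Unused.
#' @return Tibble with `n_communities`, `modularity`, `n_levels`,
#'   `largest_community`, `seed`.
#' @export
glance.louvain_result <- function(x, ...) {
  tibble(n_communities = x$n_communities,
         modularity = x$modularity,
         n_levels = x$n_levels,
         largest_community = x$community_sizes[1],
         seed = x$seed)
}

#' Tidy module eigengenes to long format
#'
#' @param x A `module_eigengenes` tibble.
#' @param ... Unused.
#' @return Tibble with `module`, `sample_id`, `eigengene`.
#' @export
tidy.module_eigengenes <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -c("module", "variance_explained"),
                      names_to = "sample_id", values_to = "eigengene")
}

#' One-row-per-module summary of eigengenes
#'
#' @param x A `module_eigengenes` tibble.
#' @param ... Unused.
#' @return Tibble with `module` and `variance_explained`.
#' @export
glance.module_eigengenes <- function(x, ...) {
  dplyr::select(as_tibble(x), "module", "variance_explained")
}

#' Tidy a run summary to stage-count rows
#'
#' @param x A `run_summary` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with `quantity` and `value`.
#' @export
tidy.run_summary <- function(x, ...) {
  tibble(
    quantity = c("genes", "samples", "genes_selected", "modules",
                 "grey_genes", "target_module_size", "core_nodes",
                 "core_edges", "communities"),
    value = c(x$n_genes, x$n_samples, x$n_genes_selected, x$n_modules,
              x$n_grey, x$target_module_size, x$core_nodes, x$core_edges,
              x$n_communities)
  )
}
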