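# Over-representation analysis: hypergeometric upper-tail tests of group
# vs term overlap with Benjamini-Hochberg correction per group.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. Evaluated through the stable log-space tail of
#' [stats::phyper()]; `k = 0` gives exactly 1.
#'
#' @param k Observed overlap.
#' @param n Query (group) size.
#' @param K Term size.
#' @param N Universe size.
#' @return The p-value.
#' @export
hypergeometric_p <- function(k, n, K, N) {
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort("Bounds violated: need 0 <= k <= min(n, K) and n, K <= N.")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, return in the input
#' order (wraps [stats::p.adjust()] with input validation).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: term id, description, then one gene per field.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `term_id`, `description` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("Line %d of %s has fewer than 3 fields.", short[1], path))
  }
  tibble(term_id = vapply(fields, `[`, "", 1),
         description = vapply(fields, `[`, "", 2),
         genes = purrr::map(fields, ~ .x[-(1:2)]))
}

#' Write gene sets to a GMT file
#'
#' @param terms Tibble with `term_id`, `description`, `genes` list-column.
#' @param path Output path.
#' @return `terms`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- purrr::pmap_chr(terms[c("term_id", "description", "genes")],
                           function(term_id, description, genes) {
    paste(c(term_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(terms)
}

# Accept groups as a named list of gene vectors or a 2-column data frame
# (first column gene/node id, a `group`/`community`/`module` column).
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    gcol <- intersect(c("group", "community", "module", "block"), names(groups))[1]
    icol <- intersect(c("gene_id", "node", "gene"), names(groups))[1]
    if (is.na(gcol) || is.na(icol)) {
      abort("Group data frame needs an id column (gene_id/node) and a group column (group/community/module).")
    }
    return(split(as.character(groups[[icol]]), groups[[gcol]]))
  }
  if (!is.list(groups) || is.null(names(groups))) {
    abort("`groups` must be a named list of gene sets or a data frame.")
  }
  groups
}

as_term_list <- function(terms) {
  if (is.data.frame(terms)) {
    return(list(ids = as.character(terms$term_id),
                names = as.character(terms$description %||% terms$term_id),
                genes = terms$genes))
  }
  abort("`terms` must be a tibble with term_id, description, genes (see read_gmt()).")
}

#' Over-representation analysis of gene groups against annotation terms
#'
#' One hypergeometric test per (group, term) pair: group and term
#' memberships are intersected with the universe, genes outside the
#' universe are dropped (with a message giving the count), and
#' Benjamini-Hochberg correction is applied within each group's family of
#' terms (set `family = "global"` for a single family across all
#' groups). Rows are sorted by adjusted p within group.
#'
#' @param groups Named list of gene sets, or a data frame with an id
#'   column and a group column (e.g. a Louvain membership or module
#'   assignment tibble).
#' @param terms Term tibble from [read_gmt()] or [simulate_annotations()].
#' @param universe Character vector of gene ids forming the test
#'   universe, typically all genes in the analysed network.
#' @param family `"per_group"` (default) or `"global"` BH family.
#' @return Tibble of class `enrichment_result` with `group`, `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p`, `p_adj` and an `overlap`
#'   list-column of overlapping genes.
#' @export
enrich_groups <- function(groups, terms, universe,
                          family = c("per_group", "global")) {
  family <- match.arg(family)
  groups <- as_group_list(groups)
  tl <- as_term_list(terms)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  N <- length(universe)
  dropped <- sum(vapply(groups, function(g) sum(!(g %in% universe)), 0L))
  if (dropped > 0) {
    inform(sprintf("%d group gene(s) outside the universe were dropped.", dropped))
  }
  term_genes <- purrr::map(tl$genes, ~ intersect(unique(.x), universe))
  rows <- purrr::imap(groups, function(gset, gname) {
    q <- intersect(unique(gset), universe)
    n <- length(q)
    k <- vapply(term_genes, function(tg) length(intersect(tg, q)), 0L)
    K <- lengths(term_genes)
    p <- hypergeometric_p(k, n, K, N)
    tibble(group = gname, term_id = tl$ids, term_name = tl$names,
           k = k, n = n, K = K, N = N, p = p,
           overlap = purrr::map(term_genes, ~ intersect(.x, q)))
  })
  out <- dplyr::bind_rows(rows)
  if (family == "per_group") {
    out <- dplyr::mutate(dplyr::group_by(out, .data$group),
                         p_adj = bh_adjust(.data$p))
    out <- dplyr::ungroup(out)
  } else {
    out$p_adj <- bh_adjust(out$p)
  }
  out <- dplyr::arrange(out, .data$group, .data$p_adj, .data$p, .data$term_id)
  out <- dplyr::select(out, "group", "term_id", "term_name", "k", "n", "K",
                       "N", "p", "p_adj", "overlap")
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Write an enrichment table to TSV
#'
#' The `overlap` list-column is collapsed to a comma-separated string.
#'
#' @param x An `enrichment_result`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  flat <- dplyr::mutate(as_tibble(x),
                        overlap = purrr::map_chr(.data$overlap, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(x)
}
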