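#' Construct an undirected weighted graph
#'
#' The central container for protein-protein interaction networks and their
#' Louvain aggregates. A graph holds a canonical edge tibble (`from` <
#' `to`, positive weights, no duplicates), an ordered node vector, and a
#' per-node self-loop weight used only by community aggregation: a stored
#' self weight `w` contributes `2w` to its node's degree and `w` to the
#' total edge weight `m`, so the identity `sum(k_i) = 2m` holds exactly at
#' every stage.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight` (default 1). Both orientations of a pair are merged, keeping
#'   the maximum weight, with a warning. Self pairs are rejected.
#' @param nodes Optional character vector of node ids; the union with the
#'   edge endpoints is used, so isolated nodes can be represented.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight) | edges$weight <= 0)) {
    bad <- which(!is.finite(edges$weight) | edges$weight <= 0)[1]
    abort(sprintf("Edge %d (%s -- %s) has non-positive weight %s.",
                  bad, edges$from[bad], edges$to[bad], edges$weight[bad]))
  }
  if (any(edges$from == edges$to)) {
    bad <- which(edges$from == edges$to)[1]
    abort(sprintf("Self pair '%s -- %s' is not allowed in input graphs.",
                  edges$from[bad], edges$to[bad]))
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    merged <- tapply(edges$weight, key, max)
    differ <- tapply(edges$weight, key, function(w) length(unique(w)) > 1)
    if (any(differ)) {
      warn(sprintf("%d duplicated node pair(s) with differing weights; keeping the maximum.",
                   sum(differ)))
    } else {
      warn(sprintf("%d duplicated node pair(s) merged.", sum(duplicated(key))))
    }
    keys <- names(merged)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- tibble(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    weight = as.numeric(merged))
  } else {
    edges <- tibble(from = a, to = b, weight = edges$weight)
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  new_weighted_graph(all_nodes, edges,
                     self = stats::setNames(numeric(length(all_nodes)), all_nodes))
}

# Low-level constructor; `self` holds aggregation self-loop weights.
new_weighted_graph <- function(nodes, edges, self) {
  structure(list(nodes = nodes, edges = edges, self = self),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph: %d nodes, %d edges, m = %g>\n",
              length(x$nodes), nrow(x$edges), graph_total_weight(x)))
  invisible(x)
}

#' Total edge weight m of a graph
#'
#' `m = (1/2) * sum_ij A_ij`, counting each undirected edge once and each
#' stored self-loop weight once.
#'
#' @param g A `weighted_graph`.
#' @return A single number.
#' @export
graph_total_weight <- function(g) {
  sum(g$edges$weight) + sum(g$self)
}

#' Node degrees of a weighted graph
#'
#' Weighted degree is `k_i = sum_j A_ij` (a self-loop contributes twice);
#' unweighted degree is the incident edge count.
#'
#' @param g A `weighted_graph`.
#' @return Tibble with `node`, `weighted_degree`, `unweighted_degree`, in
#'   graph node order.
#' @export
node_degrees <- function(g) {
  wk <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  uk <- stats::setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    wt <- tapply(c(g$edges$weight, g$edges$weight), c(g$edges$from, g$edges$to), sum)
    wk[names(wt)] <- wt
    ct <- table(c(g$edges$from, g$edges$to))
    uk[names(ct)] <- as.integer(ct)
  }
  wk <- wk + 2 * g$self[g$nodes]
  uk <- uk + as.integer(g$self[g$nodes] > 0)
  tibble(node = g$nodes, weighted_degree = unname(wk),
         unweighted_degree = unname(uk))
}

#' Load a weighted edge list from TSV
#'
#' Expects at least two columns (node pair) and an optional third column of
#' weights (default 1). A header row is auto-detected (non-numeric third
#' field, or a first field matching common header names). Duplicate pairs
#' in either orientation are merged keeping the maximum weight; self pairs
#' and non-positive weights are errors reported with their line number.
#'
#' @param path Path to a tab-separated edge list.
#' @param weight_scale Optional divisor applied to weights, e.g. 1000 to
#'   map STRING combined scores onto (0, 1].
#' @return A `weighted_graph`.
#' @export
load_edge_list <- function(path, weight_scale = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("Edge list %s is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("Line %d of %s has fewer than 2 fields.",
                  which(lengths(fields) < 2)[1], path))
  }
  first <- fields[[1]]
  header_names <- c("from", "to", "node_a", "node_b", "node1", "node2",
                    "source", "target", "protein1", "protein2")
  has_header <- (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) ||
    tolower(first[1]) %in% header_names
  offset <- 0L
  if (has_header) {
    fields <- fields[-1]
    offset <- 1L
    if (length(fields) == 0) abort(sprintf("Edge list %s has a header but no edges.", path))
  }
  from <- vapply(fields, `[`, "", 1)
  to <- vapply(fields, `[`, "", 2)
  w_raw <- vapply(fields, function(f) if (length(f) >= 3) f[3] else "1", "")
  weight <- suppressWarnings(as.numeric(w_raw))
  if (anyNA(weight)) {
    bad <- which(is.na(weight))[1]
    abort(sprintf("Non-numeric weight '%s' on line %d of %s.",
                  w_raw[bad], bad + offset, path))
  }
  if (!is.null(weight_scale)) weight <- weight / weight_scale
  if (any(weight <= 0)) {
    bad <- which(weight <= 0)[1]
    abort(sprintf("Non-positive weight on line %d of %s.", bad + offset, path))
  }
  if (any(from == to)) {
    bad <- which(from == to)[1]
    abort(sprintf("Self pair '%s' on line %d of %s.", from[bad], bad + offset, path))
  }
  weighted_graph(tibble(from = from, to = to, weight = weight))
}

#' Write a graph's edge list to TSV
#'
#' @param g A `weighted_graph`.
#' @param path Output path. Columns `from`, `to`, `weight` with a header.
#' @return `g`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  readr::write_tsv(g$edges, path)
  invisible(g)
}

#' Extract the hub core of a graph by degree threshold
#'
#' Retains the induced subgraph on nodes whose degree in the *original*
#' graph strictly exceeds `threshold`. Degrees are not recomputed between
#' selection and induction: the contract is a single pass, so the result
#' may contain nodes whose post-filter degree falls below the threshold,
#' may be disconnected, or may be empty (warning).
#'
#' @param g A `weighted_graph`.
#' @param threshold Strict lower bound on degree (default 200).
#' @param mode `"weighted"` (sum of incident weights, default) or
#'   `"unweighted"` (incident edge count).
#' @return The induced `weighted_graph` on the surviving nodes.
#' @export
filter_by_degree <- function(g, threshold = 200, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  deg <- node_degrees(g)
  k <- if (mode == "weighted") deg$weighted_degree else deg$unweighted_degree
  keep <- deg$node[k > threshold]
  if (length(keep) == 0) {
    warn(sprintf("No node has %s degree > %g; returning an empty graph.",
                 mode, threshold))
  }
  induce_subgraph(g, keep, warn_empty = FALSE)
}

#' Induced subgraph on a gene set
#'
#' @param g A `weighted_graph`.
#' @param gene_set Character vector of node ids; the intersection with the
#'   graph's nodes is used.
#' @param warn_empty Warn when the intersection is empty (default TRUE).
#' @return The induced `weighted_graph`.
#' @export
induce_subgraph <- function(g, gene_set, warn_empty = TRUE) {
  keep <- intersect(g$nodes, as.character(gene_set))
  if (length(keep) == 0 && warn_empty) {
    warn("Gene set does not intersect the graph's nodes; returning an empty graph.")
  }
  edges <- dplyr::filter(g$edges, .data$from %in% keep & .data$to %in% keep)
  new_weighted_graph(sort(keep), edges, self = g$self[sort(keep)])
}

# Indexed form used by the Louvain engine: integer endpoints and a
# per-node incidence list, built once per graph.
graph_index <- function(g) {
  n <- length(g$nodes)
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  w <- g$edges$weight
  self <- unname(g$self[g$nodes])
  nbr <- vector("list", n)
  nbr_w <- vector("list", n)
  if (length(ei) > 0) {
    inc_node <- c(ei, ej)
    inc_other <- c(ej, ei)
    inc_w <- c(w, w)
    ord <- order(inc_node)
    split_idx <- split(seq_along(inc_node)[ord], inc_node[ord])
    for (nm in names(split_idx)) {
      i <- as.integer(nm)
      nbr[[i]] <- inc_other[split_idx[[nm]]]
      nbr_w[[i]] <- inc_w[split_idx[[nm]]]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(nbr[[i]])) {
      nbr[[i]] <- integer(0)
      nbr_w[[i]] <- numeric(0)
    }
  }
  k <- vapply(seq_len(n), function(i) sum(nbr_w[[i]]), 0) + 2 * self
  list(n = n, nodes = g$nodes, ei = ei, ej = ej, w = w, self = self,
       nbr = nbr, nbr_w = nbr_w, k = k, m = sum(w) + sum(self))
}
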