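# Independent oracles and fixture builders shared across tests.

# Direct double-sum modularity: Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m)
# delta(c_i, c_j), evaluated on a dense matrix. Deliberately naive and
# independent of the package's community bookkeeping.
modularity_direct <- function(g, membership) {
  nodes <- g$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$edges) > 0) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges$from[r]; j <- g$edges$to[r]; w <- g$edges$weight[r]
      A[i, j] <- A[i, j] + w
      A[j, i] <- A[j, i] + w
    }
  }
  diag(A) <- diag(A) + 2 * g$self[nodes]
  k <- rowSums(A)
  m <- sum(A) / 2
  memb <- membership[nodes]
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Erdos-Renyi weighted graph with character node ids; guarantees >= 1 edge.
random_weighted_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[1] <- TRUE
    nodes <- sprintf("v%02d", seq_len(n))
    weighted_graph(data.frame(from = nodes[pairs[keep, 1]],
                              to = nodes[pairs[keep, 2]],
                              weight = stats::runif(sum(keep), 0.1, 2)),
                   nodes = nodes)
  })
}

random_partition <- function(g, k = 3, seed = 1) {
  withr::with_seed(seed, {
    stats::setNames(sample.int(k, length(g$nodes), replace = TRUE), g$nodes)
  })
}

# Fraction of planted (non-background) genes recovered after greedily
# matching detected labels to planted modules.
best_match_agreement <- function(planted, detected) {
  keep <- planted != "none"
  tab <- table(planted[keep], detected[keep])
  det <- setdiff(colnames(tab), "grey")
  correct <- 0
  used <- character(0)
  for (m in rownames(tab)) {
    if (length(det) == 0) break
    sc <- tab[m, det, drop = TRUE]
    sc[det %in% used] <- -1
    best <- det[which.max(sc)]
    correct <- correct + tab[m, best]
    used <- c(used, best)
  }
  correct / sum(tab)
}

# --- small named fixtures ------------------------------------------------

fix_single_edge <- function() weighted_graph(data.frame(from = "a", to = "b"))

fix_two_disjoint_edges <- function() {
  weighted_graph(data.frame(from = c("a", "c"), to = c("b", "d")))
}

fix_triangle <- function(nodes = c("a", "b", "c"), w = 1) {
  weighted_graph(data.frame(from = nodes[c(1, 2, 3)], to = nodes[c(2, 3, 1)],
                            weight = w))
}

fix_two_triangles <- function() {
  weighted_graph(data.frame(from = c("a", "b", "c", "d", "e", "f"),
                            to = c("b", "c", "a", "e", "f", "d")))
}

fix_path3 <- function() {
  weighted_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
}

fix_star <- function(n_leaves = 5) {
  weighted_graph(data.frame(from = "hub", to = paste0("leaf", seq_len(n_leaves))))
}

fix_k5 <- function() {
  pairs <- t(utils::combn(paste0("v", 1:5), 2))
  weighted_graph(data.frame(from = pairs[, 1], to = pairs[, 2]))
}

fix_clique_pair <- function() {
  # K3 (a,b,c) + K4 (p,q,r,s), disjoint
  k3 <- t(utils::combn(c("a", "b", "c"), 2))
  k4 <- t(utils::combn(c("p", "q", "r", "s"), 2))
  weighted_graph(data.frame(from = c(k3[, 1], k4[, 1]),
                            to = c(k3[, 2], k4[, 2])))
}

# Suite of <= 8 node fixtures for oracle-equivalence testing; cliques
# flag marks graphs whose optimum is the disjoint-clique partition.
small_fixture_suite <- function() {
  list(
    list(name = "single_edge", g = fix_single_edge(), cliques = TRUE),
    list(name = "two_disjoint_edges", g = fix_two_disjoint_edges(), cliques = TRUE),
    list(name = "two_triangles", g = fix_two_triangles(), cliques = TRUE),
    list(name = "clique_pair_k3_k4", g = fix_clique_pair(), cliques = TRUE),
    list(name = "path3", g = fix_path3(), cliques = FALSE),
    list(name = "star5", g = fix_star(5), cliques = FALSE),
    list(name = "k5", g = fix_k5(), cliques = FALSE),
    list(name = "random7", g = random_weighted_graph(7, 0.5, seed = 11), cliques = FALSE),
    list(name = "random8", g = random_weighted_graph(8, 0.4, seed = 12), cliques = FALSE)
  )
}
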