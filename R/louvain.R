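# Weighted Louvain community detection, written from first principles
# around the modularity Q and its incremental form dQ. The engine works on
# an indexed graph (graph_index) with integer community labels; exported
# functions speak tibbles.

# Coerce a user partition (tibble with node/community, or named vector) to
# an integer membership vector aligned with g$nodes.
as_membership <- function(g, partition) {
  if (is.data.frame(partition)) {
    if (!all(c("node", "community") %in% names(partition))) {
      abort("Partition data frame must have columns `node` and `community`.")
    }
    lab <- stats::setNames(partition$community, as.character(partition$node))
  } else {
    if (is.null(names(partition))) {
      if (length(partition) != length(g$nodes)) {
        abort("Unnamed partition must have one label per graph node.")
      }
      lab <- stats::setNames(partition, g$nodes)
    } else {
      lab <- partition
    }
  }
  if (!setequal(names(lab), g$nodes) || length(lab) != length(g$nodes)) {
    abort("Partition must cover exactly the graph's nodes, each once.")
  }
  as.integer(factor(lab[g$nodes]))
}

# Per-community bookkeeping: Sin_c = sum of A_ij over ordered pairs inside
# c (2x each internal edge + 2x stored self weights); Stot_c = sum of
# member degrees. sum(Stot) == 2m always.
community_sums <- function(gi, memb) {
  ncomm <- max(memb)
  sin <- numeric(ncomm)
  stot <- numeric(ncomm)
  if (length(gi$ei) > 0) {
    same <- memb[gi$ei] == memb[gi$ej]
    if (any(same)) {
      s <- tapply(2 * gi$w[same], memb[gi$ei][same], sum)
      sin[as.integer(names(s))] <- s
    }
  }
  if (any(gi$self > 0)) {
    s <- tapply(2 * gi$self, memb, sum)
    sin[as.integer(names(s))] <- sin[as.integer(names(s))] + s
  }
  st <- tapply(gi$k, memb, sum)
  stot[as.integer(names(st))] <- st
  list(sin = sin, stot = stot)
}

modularity_from_sums <- function(sums, m) {
  sum(sums$sin / (2 * m) - (sums$stot / (2 * m))^2)
}

#' Modularity of a partition
#'
#' Evaluates `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`
#' via the equivalent per-community form
#' `sum_c (Sin_c / 2m - (Stot_c / 2m)^2)`, where `Sin_c` sums `A_ij` over
#' ordered node pairs inside community `c` and `Stot_c` sums member
#' degrees. Q lies in `[-1, 1]`; the one-community partition of any
#' loop-free graph has Q = 0.
#'
#' @param g A [weighted_graph()] with positive total weight.
#' @param partition Tibble with columns `node` and `community`, or a vector
#'   of labels named by node.
#' @return A single number.
#' @export
modularity <- function(g, partition) {
  if (length(g$nodes) == 0) abort("Graph has no nodes.")
  m <- graph_total_weight(g)
  if (m <= 0) abort("Modularity is undefined for a graph with total weight 0.")
  gi <- graph_index(g)
  memb <- as_membership(g, partition)
  modularity_from_sums(community_sums(gi, memb), m)
}

#' Modularity change for moving one node
#'
#' Exact `dQ` for reassigning `node` from its current community to
#' `target_community`, computed as the removal gain plus the insertion
#' gain from the community bookkeeping (`Sin`, `Stot`, `k_i,in`). Matches
#' a from-scratch recomputation `Q(after) - Q(before)` to floating-point
#' accuracy; moving a node into its own community gives exactly 0.
#'
#' @inheritParams modularity
#' @param node Node id to move.
#' @param target_community Label of an existing community in `partition`.
#' @return The modularity change as a single number.
#' @export
delta_q_move <- function(g, partition, node, target_community) {
  m <- graph_total_weight(g)
  if (m <= 0) abort("Modularity is undefined for a graph with total weight 0.")
  gi <- graph_index(g)
  memb <- as_membership(g, partition)
  # recover the user's labelling so target_community can be matched
  if (is.data.frame(partition)) {
    user_lab <- stats::setNames(partition$community, as.character(partition$node))
  } else if (!is.null(names(partition))) {
    user_lab <- partition
  } else {
    user_lab <- stats::setNames(partition, g$nodes)
  }
  i <- match(as.character(node), gi$nodes)
  if (is.na(i)) abort(sprintf("Node '%s' is not in the graph.", node))
  tgt_nodes <- names(user_lab)[user_lab == target_community]
  if (length(tgt_nodes) == 0) {
    abort(sprintf("Target community '%s' does not exist in the partition.",
                  target_community))
  }
  target <- memb[match(tgt_nodes[1], gi$nodes)]
  src <- memb[i]
  if (target == src) return(0)
  sums <- community_sums(gi, memb)
  k_i <- gi$k[i]
  nbr_comm <- memb[gi$nbr[[i]]]
  k_in_src <- sum(gi$nbr_w[[i]][nbr_comm == src])
  k_in_tgt <- sum(gi$nbr_w[[i]][nbr_comm == target])
  s <- gi$self[i]
  m2 <- 2 * m
  q_src_before <- sums$sin[src] / m2 - (sums$stot[src] / m2)^2
  q_tgt_before <- sums$sin[target] / m2 - (sums$stot[target] / m2)^2
  q_src_after <- (sums$sin[src] - 2 * k_in_src - 2 * s) / m2 -
    ((sums$stot[src] - k_i) / m2)^2
  q_tgt_after <- (sums$sin[target] + 2 * k_in_tgt + 2 * s) / m2 -
    ((sums$stot[target] + k_i) / m2)^2
  (q_src_after + q_tgt_after) - (q_src_before + q_tgt_before)
}

# Core greedy sweep. memb: integer labels. Returns list(memb, moved).
# Each node is offered its neighbouring communities; it takes the one with
# the largest positive dQ (ties: lowest community id), else stays.
louvain_sweep_until_stable <- function(gi, memb, shuffle = TRUE, tol = 1e-12) {
  m <- gi$m
  stot <- numeric(gi$n)
  st <- tapply(gi$k, memb, sum)
  stot[as.integer(names(st))] <- st
  moved_any <- FALSE
  repeat {
    order_nodes <- if (shuffle) sample.int(gi$n) else seq_len(gi$n)
    moves <- 0L
    for (i in order_nodes) {
      src <- memb[i]
      k_i <- gi$k[i]
      nbrs <- gi$nbr[[i]]
      if (length(nbrs) == 0) next
      # provisional removal of i from its community
      stot[src] <- stot[src] - k_i
      nbr_comm <- memb[nbrs]
      k_in <- tapply(gi$nbr_w[[i]], nbr_comm, sum)
      cand <- as.integer(names(k_in))
      if (!(src %in% cand)) {
        cand <- c(cand, src)
        k_in <- c(k_in, 0)
      }
      # dQ(C) differs from score(C) = k_in - stot_C * k_i / 2m by terms
      # independent of C (node self-loop, k_i^2 penalty)
      score <- as.numeric(k_in) - stot[cand] * k_i / (2 * m)
      stay <- score[cand == src]
      best_idx <- which(score == max(score))
      best <- cand[best_idx][which.min(cand[best_idx])]
      best_score <- max(score)
      if (best != src && best_score > stay + tol) {
        memb[i] <- best
        stot[best] <- stot[best] + k_i
        moves <- moves + 1L
        moved_any <- TRUE
      } else {
        stot[src] <- stot[src] + k_i
      }
    }
    if (moves == 0L) break
  }
  list(memb = memb, moved = moved_any)
}

#' One local-moving phase of the Louvain algorithm
#'
#' Starting from the supplied partition, repeatedly sweeps over nodes in a
#' seeded random order, greedily reassigning each node to the neighbouring
#' community with the largest strictly positive modularity gain, until a
#' full sweep makes no move. Every accepted move strictly increases Q.
#'
#' @inheritParams modularity
#' @param seed Integer seed for the sweep order; `NULL` uses sorted node
#'   order (fully deterministic without randomness).
#' @return List with `partition` (tibble `node`, `community`) and
#'   `improved` (logical: was any move made).
#' @export
local_moving_phase <- function(g, partition, seed = NULL) {
  gi <- graph_index(g)
  if (gi$m <= 0) abort("Graph has no edge weight; nothing to optimise.")
  memb <- as_membership(g, partition)
  run <- function() louvain_sweep_until_stable(gi, memb, shuffle = !is.null(seed))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(partition = tibble(node = gi$nodes, community = res$memb),
       improved = res$moved)
}

#' Aggregate communities into super-nodes
#'
#' Builds the condensed graph with one super-node per community:
#' inter-community edge weights are summed, and each community's internal
#' weight (internal edges plus member self-loops) is stored as the
#' super-node's self-loop so that
#' `modularity(aggregate_graph(g, p), identity) == modularity(g, p)`
#' exactly.
#'
#' @inheritParams modularity
#' @return A `weighted_graph` whose nodes are the community labels (as
#'   character).
#' @export
aggregate_graph <- function(g, partition) {
  gi <- graph_index(g)
  memb <- as_membership(g, partition)
  labs <- sort(unique(memb))
  name_of <- stats::setNames(as.character(labs), labs)
  self_w <- stats::setNames(numeric(length(labs)), as.character(labs))
  # internal edge weight counted once per edge + member self weights
  if (length(gi$ei) > 0) {
    same <- memb[gi$ei] == memb[gi$ej]
    if (any(same)) {
      s <- tapply(gi$w[same], memb[gi$ei][same], sum)
      self_w[name_of[names(s)]] <- self_w[name_of[names(s)]] + as.numeric(s)
    }
  }
  if (any(gi$self > 0)) {
    s <- tapply(gi$self, memb, sum)
    self_w[name_of[names(s)]] <- self_w[name_of[names(s)]] + as.numeric(s)
  }
  edges <- tibble(from = character(0), to = character(0), weight = numeric(0))
  if (length(gi$ei) > 0) {
    cross <- memb[gi$ei] != memb[gi$ej]
    if (any(cross)) {
      ca <- pmin(memb[gi$ei][cross], memb[gi$ej][cross])
      cb <- pmax(memb[gi$ei][cross], memb[gi$ej][cross])
      key <- paste(ca, cb, sep = "\r")
      wsum <- tapply(gi$w[cross], key, sum)
      parts <- strsplit(names(wsum), "\r", fixed = TRUE)
      edges <- tibble(from = name_of[vapply(parts, `[`, "", 1)],
                      to = name_of[vapply(parts, `[`, "", 2)],
                      weight = as.numeric(wsum))
    }
  }
  nodes <- as.character(labs)
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  new_weighted_graph(sort(nodes), edges, self = self_w[sort(nodes)])
}

#' Louvain community detection
#'
#' Full two-phase Louvain: starting from singleton communities, alternate
#' [local_moving_phase()] (greedy positive-gain node reassignment in a
#' seeded random sweep order) with [aggregate_graph()] (communities
#' collapsed to super-nodes), until a level improves Q by less than
#' `min_gain`. The hierarchy and the Q trajectory are retained; final
#' communities are relabelled `0, 1, ...` by decreasing size.
#'
#' @param g A [weighted_graph()] with positive total weight.
#' @param seed Integer seed controlling sweep order; results are
#'   reproducible for a fixed seed.
#' @param min_gain Convergence tolerance on the per-level Q gain.
#' @param deterministic If `TRUE`, sweep nodes in sorted id order instead
#'   of a seeded shuffle.
#' @return An object of class `louvain_result`: a list with `membership`
#'   (tibble `node`, `community`), `n_communities`, `modularity`,
#'   `q_trajectory` (Q after each level), `levels` (per-level memberships
#'   on the original nodes), `community_sizes`, `seed`, `n_levels`.
#' @export
run_louvain <- function(g, seed = 0, min_gain = 1e-10, deterministic = FALSE) {
  if (length(g$nodes) == 0) abort("Cannot run Louvain on an empty graph.")
  if (graph_total_weight(g) <= 0) {
    abort("Cannot run Louvain on a graph with total weight 0.")
  }
  run <- function() {
    current <- g
    node_to_comm <- stats::setNames(seq_along(g$nodes), g$nodes) # orig node -> current super-node index
    levels <- list()
    q_traj <- numeric(0)
    q_prev <- -Inf
    repeat {
      gi <- graph_index(current)
      res <- louvain_sweep_until_stable(gi, seq_len(gi$n), shuffle = !deterministic)
      # canonical labels 1..K so they agree with aggregate_graph's node names
      memb <- as.integer(factor(res$memb))
      q <- modularity_from_sums(community_sums(gi, memb), gi$m)
      flat <- memb[node_to_comm]
      if (length(q_traj) > 0 && q - q_prev < min_gain) break
      levels[[length(levels) + 1]] <- flat
      q_traj <- c(q_traj, q)
      q_prev <- q
      if (!res$moved && length(q_traj) > 1) break
      agg <- aggregate_graph(current, tibble(node = gi$nodes, community = memb))
      # map original nodes through: community label -> position in agg nodes
      node_to_comm <- match(as.character(flat), agg$nodes)
      names(node_to_comm) <- g$nodes
      if (length(agg$nodes) == length(current$nodes)) break
      current <- agg
    }
    final <- levels[[length(levels)]]
    sizes <- table(final)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
    community <- unname(relabel[as.character(final)])
    structure(list(
      membership = tibble(node = g$nodes, community = community),
      n_communities = length(sizes),
      modularity = q_traj[length(q_traj)],
      q_trajectory = q_traj,
      levels = levels,
      community_sizes = as.integer(sort(table(community), decreasing = TRUE)),
      seed = seed,
      n_levels = length(levels)
    ), class = "louvain_result")
  }
  if (deterministic) run() else withr::with_seed(seed, run())
}

#' @export
print.louvain_result <- function(x, ...) {
  cat(sprintf("<louvain_result: %d communities, Q = %.4f, %d level(s)>\n",
              x$n_communities, x$modularity, x$n_levels))
  cat("community sizes:", paste(x$community_sizes, collapse = ", "), "\n")
  invisible(x)
}

# Enumerate all set partitions of n items as restricted growth strings.
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, max_lab) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(max_lab + 1L)) {
      recurse(c(assign, lab), max(max_lab, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

#' Exhaustive maximum-modularity partition (small-graph oracle)
#'
#' Enumerates every set partition of the nodes (Bell-number growth, so
#' capped at `max_nodes`) and returns a global modularity maximiser. Used
#' as an independent optimum oracle for [run_louvain()] on small fixtures.
#'
#' @param g A `weighted_graph` with at most `max_nodes` nodes.
#' @param max_nodes Hard cap on the enumeration (default 8).
#' @return List with `partition` (tibble `node`, `community`) and `q`, the
#'   optimal modularity.
#' @export
brute_force_max_modularity <- function(g, max_nodes = 8) {
  n <- length(g$nodes)
  if (n == 0) abort("Graph has no nodes.")
  if (n > max_nodes) {
    abort(sprintf("Graph has %d nodes; brute force is capped at %d.", n, max_nodes))
  }
  m <- graph_total_weight(g)
  if (m <= 0) abort("Modularity is undefined for a graph with total weight 0.")
  gi <- graph_index(g)
  best_q <- -Inf
  best <- NULL
  for (memb in all_set_partitions(n)) {
    q <- modularity_from_sums(community_sums(gi, memb), m)
    if (q > best_q + 1e-15) {
      best_q <- q
      best <- memb
    }
  }
  list(partition = tibble(node = g$nodes, community = best), q = best_q)
}
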