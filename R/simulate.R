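# Synthetic-data generators with known ground truth. They emulate a
# staged single-embryo transcriptome design (3 stages x a handful of
# embryos each), a STRING-like weighted interaction graph with planted
# communities and hubs, and annotation sets with planted enrichment, so
# every downstream stage can be tested without external data.

#' Configuration for the staged expression simulator
#'
#' Counts are negative binomial with mean
#' `baseline_mean * exp(loading_g * e_{m(g),s})`, where `e_{m,s}` is the
#' planted eigengene of gene g's module at sample s's stage plus
#' per-sample Gaussian jitter, and dispersion follows the
#' mean/dispersion parameterisation `variance = mu + mu^2 / dispersion`.
#' Background genes have loading 0. The default stage trends are one
#' rising, one falling and one peaked profile across the three stages, so
#' module eigengenes track developmental stage by construction.
#'
#' @param n_modules Number of planted co-expression modules.
#' @param genes_per_module Genes per planted module.
#' @param n_background_genes Genes with no planted structure.
#' @param samples_per_stage Samples (embryos) per stage.
#' @param stages Ordered stage labels.
#' @param stage_trend Matrix `n_modules x length(stages)` of eigengene
#'   means per stage; defaults to rising / falling / peaked profiles,
#'   recycled for more modules.
#' @param loading_range Interval in `[0, 1]` for per-gene loadings;
#'   `c(0, 0)` turns every gene into background.
#' @param nb_dispersion Negative-binomial dispersion (> 0); larger means
#'   less overdispersion.
#' @param baseline_mean Expected count at eigengene value 0.
#' @param jitter_sd Standard deviation of the per-(module, sample)
#'   Gaussian jitter added to the stage trend. The default (1.0,
#'   comparable to the trend amplitude) mirrors the large within-stage
#'   variability of single-embryo transcriptomes; it also keeps planted
#'   eigengenes strongly stage-tracking yet mutually distinguishable —
#'   with near-zero jitter the rising and falling trends are exact
#'   negatives, which an unsigned correlation network provably cannot
#'   separate.
#' @param seed Integer seed; identical configs give identical output.
#' @return A validated config of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_modules = 3, genes_per_module = 50,
                                  n_background_genes = 550,
                                  samples_per_stage = 8,
                                  stages = c("8cell", "16cell", "32cell"),
                                  stage_trend = NULL,
                                  loading_range = c(0.6, 1.0),
                                  nb_dispersion = 10, baseline_mean = 100,
                                  jitter_sd = 1.0, seed = 1) {
  n_modules <- check_count(n_modules, "n_modules")
  genes_per_module <- check_count(genes_per_module, "genes_per_module")
  n_background_genes <- check_count(n_background_genes, "n_background_genes", min = 0L)
  samples_per_stage <- check_count(samples_per_stage, "samples_per_stage")
  if (length(stages) == 0) abort("`stages` must be a non-empty ordered label vector.")
  stages <- as.character(stages)
  if (is.null(stage_trend)) {
    s <- length(stages)
    base <- rbind(seq(-1, 1, length.out = s),     # rising
                  seq(1, -1, length.out = s),     # falling
                  { v <- rep(-1, s); v[ceiling(s / 2)] <- 1; v }) # peaked
    stage_trend <- base[rep(seq_len(nrow(base)), length.out = n_modules), ,
                        drop = FALSE]
  }
  stage_trend <- as.matrix(stage_trend)
  if (!all(dim(stage_trend) == c(n_modules, length(stages)))) {
    abort("`stage_trend` must have one value per (module, stage) pair.")
  }
  if (length(loading_range) != 2 || loading_range[1] > loading_range[2] ||
      loading_range[1] < 0 || loading_range[2] > 1) {
    abort("`loading_range` must be an interval within [0, 1].")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    abort("`nb_dispersion` must be a positive real.")
  }
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    abort("`baseline_mean` must be a positive real.")
  }
  structure(list(n_modules = n_modules, genes_per_module = genes_per_module,
                 n_background_genes = n_background_genes,
                 samples_per_stage = samples_per_stage, stages = stages,
                 stage_trend = stage_trend, loading_range = loading_range,
                 nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a staged count matrix with planted co-expression modules
#'
#' @param config An [expression_sim_config()].
#' @return List of class `expression_sim` with `counts` (tibble,
#'   `gene_id` + one column per sample), `samples` (tibble `sample_id`,
#'   `stage`), and `truth` (list: `gene_modules` tibble with planted
#'   module label and loading per gene — background label `"none"`;
#'   `eigengenes`, the planted module x sample eigengene matrix).
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "expression_sim_config")) {
    abort("`config` must come from expression_sim_config().")
  }
  withr::with_seed(config$seed, {
    n_samples <- config$samples_per_stage * length(config$stages)
    sample_id <- sprintf("s%02d", seq_len(n_samples))
    stage <- rep(config$stages, each = config$samples_per_stage)
    # planted eigengene per (module, sample): stage trend + jitter
    eig <- matrix(0, config$n_modules, n_samples,
                  dimnames = list(paste0("M", seq_len(config$n_modules)), sample_id))
    for (mod in seq_len(config$n_modules)) {
      eig[mod, ] <- config$stage_trend[mod, match(stage, config$stages)] +
        stats::rnorm(n_samples, sd = config$jitter_sd)
    }
    n_mod_genes <- config$n_modules * config$genes_per_module
    n_genes <- n_mod_genes + config$n_background_genes
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    module <- c(rep(rownames(eig), each = config$genes_per_module),
                rep("none", config$n_background_genes))
    loading <- c(stats::runif(n_mod_genes, config$loading_range[1],
                              config$loading_range[2]),
                 rep(0, config$n_background_genes))
    mu <- matrix(config$baseline_mean, n_genes, n_samples)
    for (g in seq_len(n_mod_genes)) {
      mu[g, ] <- config$baseline_mean * exp(loading[g] * eig[module[g], ])
    }
    counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                    size = config$nb_dispersion),
                     n_genes, n_samples,
                     dimnames = list(gene_id, sample_id))
    structure(list(
      counts = expr_as_tibble(counts),
      samples = tibble(sample_id = sample_id,
                       stage = factor(stage, levels = config$stages)),
      truth = list(
        gene_modules = tibble(gene_id = gene_id, module = module,
                              loading = loading),
        eigengenes = eig
      ),
      config = config
    ), class = "expression_sim")
  })
}

#' Configuration for the interaction-graph simulator
#'
#' A weighted stochastic block model: node pairs within a block connect
#' with probability `p_in`, pairs across blocks with `p_out`, and edge
#' weights are Uniform on `weight_range` (defaults mimic normalised
#' STRING confidence scores). The first `n_hubs_per_block` nodes of each
#' block additionally receive up to `hub_extra_degree` extra within-block
#' edges (capped by block size), injecting high-degree hub structure
#' without reweighting, so both weighted and unweighted degree filters
#' are exercised.
#'
#' @param block_sizes Planted community sizes (each `>= 2`).
#' @param p_in,p_out Within/between-block edge probabilities; a warning
#'   is raised when `p_in <= p_out` (planted structure unrecoverable).
#' @param weight_range Interval in `(0, 1]` for Uniform edge weights.
#' @param n_hubs_per_block,hub_extra_degree Hub injection parameters.
#' @param node_names Optional node ids (defaults `n0001`, ...); length
#'   must equal `sum(block_sizes)`.
#' @param seed Integer seed.
#' @return A validated config of class `ppi_sim_config`.
#' @export
ppi_sim_config <- function(block_sizes = c(60, 60), p_in = 0.3, p_out = 0.01,
                           weight_range = c(0.4, 1.0), n_hubs_per_block = 0,
                           hub_extra_degree = 0, node_names = NULL, seed = 1) {
  if (length(block_sizes) < 1 || any(block_sizes < 2)) {
    abort("`block_sizes` must all be >= 2.")
  }
  p_in <- check_prob(p_in, "p_in")
  p_out <- check_prob(p_out, "p_out")
  if (p_in <= p_out) {
    warn("p_in <= p_out: planted block structure will not be recoverable.")
  }
  if (length(weight_range) != 2 || weight_range[1] <= 0 ||
      weight_range[2] > 1 || weight_range[1] > weight_range[2]) {
    abort("`weight_range` must be an interval within (0, 1].")
  }
  n_hubs_per_block <- check_count(n_hubs_per_block, "n_hubs_per_block", min = 0L)
  hub_extra_degree <- check_count(hub_extra_degree, "hub_extra_degree", min = 0L)
  n <- sum(block_sizes)
  if (is.null(node_names)) node_names <- sprintf("n%04d", seq_len(n))
  if (length(node_names) != n || anyDuplicated(node_names)) {
    abort("`node_names` must be unique and match sum(block_sizes).")
  }
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, weight_range = weight_range,
                 n_hubs_per_block = n_hubs_per_block,
                 hub_extra_degree = hub_extra_degree,
                 node_names = as.character(node_names),
                 seed = as.integer(seed)),
            class = "ppi_sim_config")
}

#' Simulate a weighted interaction graph with planted communities
#'
#' @param config A [ppi_sim_config()].
#' @return List of class `ppi_sim` with `graph` (a [weighted_graph()])
#'   and `truth` (tibble `node`, `block`, `is_hub`).
#' @export
simulate_ppi <- function(config) {
  if (!inherits(config, "ppi_sim_config")) {
    abort("`config` must come from ppi_sim_config().")
  }
  withr::with_seed(config$seed, {
    n <- sum(config$block_sizes)
    block <- rep(seq_along(config$block_sizes), config$block_sizes)
    nodes <- config$node_names
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    p <- ifelse(block[i] == block[j], config$p_in, config$p_out)
    present <- stats::rbinom(length(p), 1, p) == 1
    ei <- i[present]; ej <- j[present]
    # hub injection: extra within-block edges for designated hubs
    hubs <- integer(0)
    if (config$n_hubs_per_block > 0 && config$hub_extra_degree > 0) {
      offset <- c(0, cumsum(config$block_sizes))
      for (b in seq_along(config$block_sizes)) {
        n_h <- min(config$n_hubs_per_block, config$block_sizes[b])
        for (h in seq_len(n_h)) {
          hub <- offset[b] + h
          hubs <- c(hubs, hub)
          mates <- setdiff(which(block == block[hub]), hub)
          key <- paste(pmin(ei, ej), pmax(ei, ej))
          cand_key <- paste(pmin(hub, mates), pmax(hub, mates))
          avail <- mates[!(cand_key %in% key)]
          take <- head(sample(avail), min(config$hub_extra_degree, length(avail)))
          if (length(take) > 0) {
            ei <- c(ei, pmin(hub, take))
            ej <- c(ej, pmax(hub, take))
          }
        }
      }
    }
    w <- stats::runif(length(ei), config$weight_range[1], config$weight_range[2])
    g <- weighted_graph(tibble(from = nodes[ei], to = nodes[ej], weight = w),
                        nodes = nodes)
    structure(list(
      graph = g,
      truth = tibble(node = nodes, block = block,
                     is_hub = seq_len(n) %in% hubs)
    ), class = "ppi_sim")
  })
}

#' Simulate annotation gene sets with planted enrichment
#'
#' Generates a GMT-compatible term-to-gene map over the universe defined
#' by a community ground truth. A `planted_fraction` of terms is
#' community-specific: each draws a fixed high fraction (default 0.9,
#' always `>= 0.8`) of its members from one community and the rest
#' uniformly; null terms draw uniformly from the whole universe.
#'
#' @param communities Tibble with `node` and `block` (or `community`)
#'   columns, e.g. the `truth` of [simulate_ppi()].
#' @param n_terms Total number of terms.
#' @param planted_fraction Fraction of terms with planted enrichment.
#' @param term_size_range Integer interval of term sizes; must fit in the
#'   universe.
#' @param in_fraction Fraction of a planted term drawn from its target
#'   community (default 0.9).
#' @param seed Integer seed.
#' @return List of class `annotation_sim` with `terms` (tibble `term_id`,
#'   `description`, `genes` list-column) and `truth` (tibble `term_id`,
#'   `planted`, `community`).
#' @export
simulate_annotations <- function(communities, n_terms = 100,
                                 planted_fraction = 0.2,
                                 term_size_range = c(10, 40),
                                 in_fraction = 0.9, seed = 1) {
  if (nrow(communities) == 0) abort("`communities` must be non-empty.")
  comm_col <- intersect(c("block", "community"), names(communities))[1]
  if (is.na(comm_col)) abort("`communities` needs a `block` or `community` column.")
  universe <- as.character(communities$node)
  labels <- communities[[comm_col]]
  n_terms <- check_count(n_terms, "n_terms")
  planted_fraction <- check_prob(planted_fraction, "planted_fraction")
  if (in_fraction < 0.8) abort("`in_fraction` must be >= 0.8 for planted terms.")
  term_size_range <- as.integer(term_size_range)
  if (max(term_size_range) > length(universe)) {
    abort("`term_size_range` exceeds the universe size.")
  }
  withr::with_seed(seed, {
    n_planted <- round(n_terms * planted_fraction)
    comm_levels <- sort(unique(labels))
    rows <- purrr::map(seq_len(n_terms), function(t) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      planted <- t <= n_planted
      if (planted) {
        target <- comm_levels[(t - 1) %% length(comm_levels) + 1]
        pool_in <- universe[labels == target]
        n_in <- min(ceiling(in_fraction * size), length(pool_in))
        genes_in <- sample(pool_in, n_in)
        pool_out <- setdiff(universe, genes_in)
        genes <- c(genes_in, sample(pool_out, min(size - n_in, length(pool_out))))
      } else {
        target <- NA
        genes <- sample(universe, size)
      }
      tibble(term_id = sprintf("T%04d", t),
             description = if (planted) sprintf("planted_comm_%s", target) else "null",
             genes = list(sort(genes)),
             planted = planted,
             community = if (planted) as.character(target) else NA_character_)
    })
    all <- dplyr::bind_rows(rows)
    structure(list(
      terms = dplyr::select(all, "term_id", "description", "genes"),
      truth = dplyr::select(all, "term_id", "planted", "community")
    ), class = "annotation_sim")
  })
}
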