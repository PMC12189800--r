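# Config-driven orchestration of the full analysis chain:
# (simulate | load) -> normalise -> MAD-select -> co-expression modules ->
# eigengene/stage correlation -> target-module PPI core -> Louvain ->
# per-community enrichment, with TSV/JSON artifacts and a run summary.

pipeline_defaults <- function() {
  list(
    # inputs (paths or in-memory objects); NULL means simulate or skip
    counts = NULL, samples = NULL, ppi = NULL, gmt = NULL, deg_tables = NULL,
    simulate = NULL,
    # normalisation
    use_raw_counts = FALSE, pseudocount = 1,
    # gene selection and co-expression
    mad_top_k = 5000, beta = NULL, beta_candidates = 1:20, r2_cut = 0.85,
    cut_height = 0.9, min_module_size = 30,
    # DEG filtering (used only when deg_tables are supplied)
    lfc_cut = 1, padj_cut = 0.05,
    # target module and PPI core
    target_module = NULL, degree_threshold = 200,
    degree_mode = "weighted", filter_scope = "induced",
    # community detection
    louvain_seed = 0, min_gain = 1e-10,
    # enrichment
    enrichment_family = "per_group", universe = "network",
    # bookkeeping
    seed = 1, out_dir = NULL
  )
}

#' Build a pipeline configuration
#'
#' Returns the default configuration with any supplied overrides. The
#' analysis parameters default to the values conventional for this kind
#' of study: top 5000 genes by MAD, DEG cuts `|log2FC| > 1` and
#' `p.adj < 0.05`, PPI degree threshold 200 (strict), soft threshold
#' chosen by scale-free fit unless overridden (e.g. `beta = 8`).
#' Unknown keys are retained so [validate_config()] can report them.
#'
#' @param ... Named overrides of the default keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' All-synthetic demonstration configuration
#'
#' A self-contained configuration that simulates the whole study design
#' at desk scale: 3 planted expression modules of 60 genes (rising,
#' falling and peaked stage trends) plus 520 background genes over
#' 3 stages x 8 samples; a weighted interaction graph over the module
#' genes, with each module's genes split into two planted blocks of 30
#' (`p_in` 0.5, `p_out` 0.02, Uniform(0.4, 1) weights); and 60 annotation
#' terms of which 30% are planted on single blocks. Selection and
#' threshold parameters are scaled to this problem size: top 200 of 300
#' genes by MAD, soft threshold 8, weighted-degree threshold 5 on the
#' module-induced subgraph. Every random draw derives from `seed`.
#'
#' @param seed Master seed for all simulation stages.
#' @return A `pipeline_config`.
#' @export
default_synthetic_config <- function(seed = 1) {
  seed <- as.integer(seed)
  expr_cfg <- expression_sim_config(
    n_modules = 3, genes_per_module = 60, n_background_genes = 520,
    samples_per_stage = 8, seed = seed
  )
  pipeline_config(
    simulate = list(
      expression = expr_cfg,
      ppi = list(blocks_per_module = 2, p_in = 0.5, p_out = 0.02,
                 weight_range = c(0.4, 1.0), seed = seed + 1000L),
      annotations = list(n_terms = 60, planted_fraction = 0.3,
                         term_size_range = c(10, 25), seed = seed + 2000L)
    ),
    mad_top_k = 200, beta = 8, min_module_size = 30, cut_height = 0.9,
    degree_threshold = 5, degree_mode = "weighted", filter_scope = "induced",
    louvain_seed = seed, seed = seed
  )
}

#' Validate a pipeline configuration
#'
#' Problems are returned as data, not raised: an empty character vector
#' means the configuration is runnable.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  known <- names(pipeline_defaults())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    problems <- c(problems, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  num_ok <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
  if (!num_ok(config$mad_top_k) || config$mad_top_k < 1) {
    problems <- c(problems, "mad_top_k must be a positive integer")
  }
  if (!is.null(config$beta) && (!num_ok(config$beta) || config$beta < 1)) {
    problems <- c(problems, "beta must be NULL or >= 1")
  }
  if (!num_ok(config$cut_height) || config$cut_height <= 0 || config$cut_height > 1) {
    problems <- c(problems, "cut_height must lie in (0, 1]")
  }
  if (!num_ok(config$min_module_size) || config$min_module_size < 2) {
    problems <- c(problems, "min_module_size must be >= 2")
  }
  if (!num_ok(config$degree_threshold) || config$degree_threshold < 0) {
    problems <- c(problems, "degree_threshold must be non-negative")
  }
  if (!num_ok(config$lfc_cut) || config$lfc_cut < 0) {
    problems <- c(problems, "lfc_cut must be non-negative")
  }
  if (!num_ok(config$padj_cut) || config$padj_cut <= 0 || config$padj_cut > 1) {
    problems <- c(problems, "padj_cut must lie in (0, 1]")
  }
  if (!config$degree_mode %in% c("weighted", "unweighted")) {
    problems <- c(problems, "degree_mode must be 'weighted' or 'unweighted'")
  }
  if (!config$filter_scope %in% c("induced", "full")) {
    problems <- c(problems, "filter_scope must be 'induced' or 'full'")
  }
  if (!config$enrichment_family %in% c("per_group", "global")) {
    problems <- c(problems, "enrichment_family must be 'per_group' or 'global'")
  }
  has_expr <- !is.null(config$counts) ||
    (!is.null(config$simulate) && !is.null(config$simulate$expression))
  if (!has_expr) {
    problems <- c(problems, "no expression input: supply counts/samples or simulate$expression")
  }
  if (!is.null(config$counts) && is.null(config$samples)) {
    problems <- c(problems, "counts supplied without a sample table")
  }
  has_ppi <- !is.null(config$ppi) ||
    (!is.null(config$simulate) && !is.null(config$simulate$ppi))
  if (!has_ppi) {
    problems <- c(problems, "no interaction network: supply ppi or simulate$ppi")
  }
  problems
}

# Build the synthetic interaction graph for a simulated run: each planted
# expression module's genes are split into `blocks_per_module` planted
# blocks, so inducing on any one module yields a multi-community core.
simulate_pipeline_ppi <- function(sim_expr, ppi_spec) {
  truth <- sim_expr$truth$gene_modules
  mod_genes <- truth$gene_id[truth$module != "none"]
  mods <- unique(truth$module[truth$module != "none"])
  bpm <- ppi_spec$blocks_per_module %||% 2
  block_sizes <- integer(0)
  ordered_nodes <- character(0)
  for (mod in mods) {
    genes <- truth$gene_id[truth$module == mod]
    split_sizes <- diff(round(seq(0, length(genes), length.out = bpm + 1)))
    block_sizes <- c(block_sizes, split_sizes)
    ordered_nodes <- c(ordered_nodes, genes)
  }
  cfg <- ppi_sim_config(
    block_sizes = block_sizes,
    p_in = ppi_spec$p_in %||% 0.5,
    p_out = ppi_spec$p_out %||% 0.02,
    weight_range = ppi_spec$weight_range %||% c(0.4, 1.0),
    n_hubs_per_block = ppi_spec$n_hubs_per_block %||% 0L,
    hub_extra_degree = ppi_spec$hub_extra_degree %||% 0L,
    node_names = ordered_nodes,
    seed = ppi_spec$seed %||% 1L
  )
  simulate_ppi(cfg)
}

resolve_counts <- function(config) {
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts)) read_count_matrix(config$counts) else config$counts
    samples <- if (is.character(config$samples)) {
      readr::read_tsv(config$samples, show_col_types = FALSE)
    } else config$samples
    samples$stage <- factor(samples$stage, levels = unique(samples$stage))
    return(list(counts = counts, samples = samples, sim = NULL))
  }
  sim <- simulate_expression(config$simulate$expression)
  list(counts = sim$counts, samples = sim$samples, sim = sim)
}

resolve_ppi <- function(config, sim_expr) {
  if (!is.null(config$ppi)) {
    g <- if (is.character(config$ppi)) load_edge_list(config$ppi) else config$ppi
    return(list(graph = g, truth = NULL))
  }
  sim <- simulate_pipeline_ppi(sim_expr, config$simulate$ppi)
  list(graph = sim$graph, truth = sim$truth)
}

resolve_terms <- function(config, ppi_truth) {
  if (!is.null(config$gmt)) {
    t <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    return(list(terms = t, truth = NULL))
  }
  spec <- config$simulate$annotations
  if (is.null(spec) || is.null(ppi_truth)) return(NULL)
  sim <- simulate_annotations(
    ppi_truth,
    n_terms = spec$n_terms %||% 60,
    planted_fraction = spec$planted_fraction %||% 0.3,
    term_size_range = spec$term_size_range %||% c(10, 25),
    seed = spec$seed %||% 1L
  )
  list(terms = sim$terms, truth = sim$truth)
}

#' Run the integrative network pipeline
#'
#' Executes the full chain on real or simulated inputs: (optional) DEG
#' filtering and contrast overlap; log-CPM (unless `use_raw_counts`);
#' MAD top-k gene selection; co-expression network with soft-threshold
#' selection (or an explicit `beta`), TOM clustering, module eigengenes
#' and module-stage correlation; selection of the target module (maximum
#' `|r|` with the latest stage, overridable via `target_module`);
#' induction of the interaction subgraph on the target module's genes and
#' strict degree filtering (`filter_scope` controls whether filtering
#' happens on the induced subgraph or the full network before
#' induction); Louvain community detection on the core; and per-community
#' over-representation analysis against the annotation sets. All stages
#' are deterministic given the configuration's seeds.
#'
#' @param config A [pipeline_config()], e.g. [default_synthetic_config()].
#' @return A list of class `run_summary`: stage-by-stage entity counts,
#'   parameter and seed echo, and the stage results themselves in
#'   `$results`. When `config$out_dir` is set, all stage outputs are
#'   written there as TSV/JSON plus a `run_summary.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("Invalid configuration:\n- ", paste(problems, collapse = "\n- ")))
  }

  # --- inputs ---------------------------------------------------------
  expr_in <- resolve_counts(config)
  counts <- expr_in$counts
  samples <- expr_in$samples
  ppi_in <- resolve_ppi(config, expr_in$sim)
  terms_in <- resolve_terms(config, ppi_in$truth)

  deg_summary <- NULL
  overlap <- NULL
  if (!is.null(config$deg_tables)) {
    tabs <- purrr::map(config$deg_tables, function(t) {
      if (is.character(t)) t <- readr::read_tsv(t, show_col_types = FALSE)
      filter_deg_table(t, lfc_cut = config$lfc_cut, padj_cut = config$padj_cut)
    })
    deg_summary <- purrr::map_int(tabs, nrow)
    if (length(tabs) >= 2) overlap <- contrast_overlap(tabs)
  }

  # --- expression -> modules ------------------------------------------
  expr <- if (config$use_raw_counts) counts else log_cpm(counts, config$pseudocount)
  k <- min(config$mad_top_k, nrow(as_expr_matrix(expr)))
  selected <- mad_select_top_k(expr, k)
  if (is.null(config$beta)) {
    st_report <- pick_soft_threshold(selected, candidates = config$beta_candidates,
                                     r2_cut = config$r2_cut, drop_constant = TRUE)
    beta <- attr(st_report, "chosen_beta")
  } else {
    st_report <- NULL
    beta <- config$beta
  }
  corr <- correlation_matrix(selected, drop_constant = TRUE)
  tom <- tom_similarity(adjacency(corr, beta))
  modules <- detect_modules(tom, min_module_size = config$min_module_size,
                            cut_height = config$cut_height)
  non_grey <- setdiff(unique(modules$module), "grey")
  if (length(non_grey) == 0) {
    abort("No co-expression module detected; cannot choose a target module.")
  }
  me <- module_eigengenes(selected, modules)
  mt <- module_trait_correlation(me, samples)

  # --- target module --------------------------------------------------
  latest <- attr(mt, "stages")[length(attr(mt, "stages"))]
  if (!is.null(config$target_module)) {
    target <- config$target_module
    if (!target %in% modules$module) {
      abort(sprintf("Requested target module '%s' was not detected.", target))
    }
  } else {
    cand <- dplyr::filter(mt, .data$stage == latest, !is.na(.data$r))
    cand <- dplyr::arrange(cand, dplyr::desc(abs(.data$r)), .data$module)
    target <- cand$module[1]
  }
  target_genes <- modules$gene_id[modules$module == target]

  # --- PPI core -------------------------------------------------------
  g <- ppi_in$graph
  if (config$filter_scope == "full") {
    core <- induce_subgraph(filter_by_degree(g, config$degree_threshold,
                                             config$degree_mode),
                            target_genes, warn_empty = FALSE)
  } else {
    core <- filter_by_degree(induce_subgraph(g, target_genes, warn_empty = FALSE),
                             config$degree_threshold, config$degree_mode)
  }
  if (length(core$nodes) == 0 || graph_total_weight(core) <= 0) {
    abort(sprintf(
      "Empty core subnetwork: no node of the '%s' module exceeds %s degree %g; halting before community detection.",
      target, config$degree_mode, config$degree_threshold))
  }

  # --- communities ----------------------------------------------------
  louvain <- run_louvain(core, seed = config$louvain_seed,
                         min_gain = config$min_gain)

  # --- enrichment -----------------------------------------------------
  enrichment <- NULL
  if (!is.null(terms_in)) {
    universe <- if (identical(config$universe, "network")) {
      core$nodes
    } else config$universe
    enrichment <- enrich_groups(louvain$membership, terms_in$terms, universe,
                                family = config$enrichment_family)
  }

  summary <- structure(list(
    n_genes = nrow(counts), n_samples = nrow(samples),
    stages = levels(samples$stage),
    deg_counts = deg_summary,
    n_genes_selected = k,
    beta = beta,
    n_modules = length(non_grey),
    module_sizes = table(modules$module)[non_grey],
    n_grey = sum(modules$module == "grey"),
    target_module = target,
    target_module_size = length(target_genes),
    core_nodes = length(core$nodes),
    core_edges = nrow(core$edges),
    n_communities = louvain$n_communities,
    community_sizes = louvain$community_sizes,
    modularity = louvain$modularity,
    n_enriched_terms = if (!is.null(enrichment)) sum(enrichment$p_adj < 0.05) else NA,
    seeds = list(master = config$seed, louvain = config$louvain_seed),
    parameters = config[c("mad_top_k", "beta", "cut_height", "min_module_size",
                          "degree_threshold", "degree_mode", "filter_scope",
                          "lfc_cut", "padj_cut", "min_gain")],
    results = list(counts = counts, samples = samples, expr_selected = selected,
                   soft_threshold = st_report, modules = modules,
                   eigengenes = me, module_trait = mt, ppi = g, core = core,
                   louvain = louvain, enrichment = enrichment,
                   overlap = overlap,
                   truth = list(expression = expr_in$sim$truth,
                                ppi = ppi_in$truth,
                                annotations = terms_in$truth))
  ), class = "run_summary")

  if (!is.null(config$out_dir)) write_run_artifacts(summary, config)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  cat(sprintf("  genes x samples: %d x %d; selected: %d; beta = %g\n",
              x$n_genes, x$n_samples, x$n_genes_selected, x$beta))
  cat(sprintf("  modules: %d (+%d grey); target: %s (%d genes)\n",
              x$n_modules, x$n_grey, x$target_module, x$target_module_size))
  cat(sprintf("  core subnetwork: %d nodes, %d edges\n", x$core_nodes, x$core_edges))
  cat(sprintf("  communities: %d (sizes %s), Q = %.4f\n", x$n_communities,
              paste(x$community_sizes, collapse = ", "), x$modularity))
  if (!is.na(x$n_enriched_terms)) {
    cat(sprintf("  enriched terms (p.adj < 0.05): %d\n", x$n_enriched_terms))
  }
  invisible(x)
}

write_run_artifacts <- function(summary, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  res <- summary$results
  write_count_matrix(res$counts, out("counts.tsv"))
  readr::write_tsv(res$samples, out("samples.tsv"))
  if (!is.null(res$soft_threshold)) {
    readr::write_tsv(as_tibble(res$soft_threshold), out("soft_threshold.tsv"))
  }
  readr::write_tsv(res$modules, out("module_assignment.tsv"))
  readr::write_tsv(as_tibble(res$eigengenes), out("eigengenes.tsv"))
  readr::write_tsv(as_tibble(res$module_trait), out("module_trait.tsv"))
  write_edge_list(res$ppi, out("ppi_edges.tsv"))
  write_edge_list(res$core, out("core_edges.tsv"))
  readr::write_tsv(res$louvain$membership, out("communities.tsv"))
  readr::write_tsv(tibble(level = seq_along(res$louvain$q_trajectory),
                          q = res$louvain$q_trajectory),
                   out("q_trajectory.tsv"))
  if (!is.null(res$enrichment)) write_enrichment(res$enrichment, out("enrichment.tsv"))
  if (!is.null(res$truth$expression)) {
    jsonlite::write_json(
      list(gene_modules = res$truth$expression$gene_modules,
           ppi_blocks = res$truth$ppi,
           annotation_truth = res$truth$annotations),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  slim <- summary[setdiff(names(summary), "results")]
  slim$module_sizes <- as.list(summary$module_sizes)
  slim$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(slim, out("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(summary)
}
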