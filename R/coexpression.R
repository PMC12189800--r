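# WGCNA-style co-expression networks: correlation -> soft-thresholded
# adjacency -> topological overlap -> hierarchical modules -> eigengenes
# -> module-trait correlation.

#' Gene-gene Pearson correlation matrix
#'
#' @param expr Expression matrix, genes x samples (tibble with `gene_id`
#'   or matrix with gene rownames). At least 3 samples.
#' @param drop_constant Constant genes have undefined correlations; by
#'   default they trigger an error naming them, with `drop_constant =
#'   TRUE` they are silently excluded with a warning.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, drop_constant = FALSE) {
  m <- as_expr_matrix(expr, "expr")
  if (ncol(m) < 3) abort("At least 3 samples are required for correlations.")
  sds <- apply(m, 1, stats::sd)
  const <- rownames(m)[sds == 0 | is.na(sds)]
  if (length(const) > 0) {
    if (!drop_constant) {
      abort(sprintf("Constant gene(s) with undefined correlation: %s",
                    paste(head(const, 10), collapse = ", ")))
    }
    warn(sprintf("Excluding %d constant gene(s).", length(const)))
    m <- m[setdiff(rownames(m), const), , drop = FALSE]
  }
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |r_ij|^beta`; raising correlations
#' to a power amplifies strong correlations and penalises weak ones. The
#' diagonal is forced to 1.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param beta Soft-threshold power, `>= 1`.
#' @return Adjacency matrix with entries in `[0, 1]` and unit diagonal.
#' @export
adjacency <- function(corr, beta) {
  if (beta < 1) abort("`beta` must be >= 1.")
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

# Scale-free topology fit: bin connectivities, regress log10 frequency on
# log10 mean connectivity, report R^2 signed by the (negated) slope so a
# scale-free (decreasing) fit scores positively.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2) return(list(r_squared = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  k_mean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 2) return(list(r_squared = NA_real_, slope = NA_real_))
  x <- log10(k_mean[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-threshold power
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' connectivities `k_i = sum_{j != i} a_ij`, and scores the fit of the
#' connectivity distribution to a scale-free law by regressing log10
#' frequency on log10 connectivity over binned `k` (signed R-squared:
#' positive when frequency decreases with connectivity). The chosen power
#' is the smallest candidate whose signed R-squared reaches `r2_cut`; if
#' none does, the power with maximal signed R-squared is chosen with a
#' warning.
#'
#' @inheritParams correlation_matrix
#' @param candidates Candidate powers (default 1..20).
#' @param r2_cut Signed R-squared needed to accept a power (default 0.85).
#' @param n_bins Histogram bins for the fit (default 10).
#' @return A tibble of class `soft_threshold_report` with columns `beta`,
#'   `r_squared`, `slope`, `mean_connectivity`; the chosen power is in
#'   `attr(, "chosen_beta")`.
#' @export
pick_soft_threshold <- function(expr, candidates = 1:20, r2_cut = 0.85,
                                n_bins = 10, drop_constant = FALSE) {
  corr <- correlation_matrix(expr, drop_constant = drop_constant)
  absr <- abs(corr)
  diag(absr) <- 0
  rows <- purrr::map(candidates, function(beta) {
    a <- absr^beta
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins = n_bins)
    tibble(beta = beta, r_squared = fit$r_squared, slope = fit$slope,
           mean_connectivity = mean(k))
  })
  report <- dplyr::bind_rows(rows)
  ok <- which(!is.na(report$r_squared) & report$r_squared >= r2_cut)
  if (length(ok) > 0) {
    chosen <- report$beta[ok[1]]
  } else {
    if (all(is.na(report$r_squared))) {
      warn("Scale-free fit undefined for every candidate power; defaulting to the smallest.")
      chosen <- candidates[1]
    } else {
      warn(sprintf("No candidate power reaches signed R^2 >= %g; using the best fit.",
                   r2_cut))
      chosen <- report$beta[which.max(report$r_squared)]
    }
  }
  attr(report, "chosen_beta") <- chosen
  attr(report, "r2_cut") <- r2_cut
  class(report) <- c("soft_threshold_report", class(report))
  report
}

#' Topological overlap similarity
#'
#' Standard unsigned TOM:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{j != i} a_ij`;
#' `TOM_ii = 1`. Genes are topologically similar when they share
#' neighbours, not merely when they are directly connected, which makes
#' `1 - TOM` a robust clustering dissimilarity.
#'
#' @param adj Adjacency matrix from [adjacency()].
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

# WGCNA's conventional module colour sequence, by decreasing module size.
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `min_module_size` are
#' relabelled `"grey"` (unassigned). Surviving modules are named by the
#' conventional colour sequence in order of decreasing size (largest =
#' `"turquoise"`).
#'
#' The default cut height of 0.9 reflects the geometry of unsigned TOM
#' dissimilarities: co-expressed genes finish merging at `1 - TOM` around
#' 0.6-0.8 while unrelated and anticorrelated-module gene pairs sit at
#' about 0.94 and above, so a cut at 0.9 lies inside the gap. Cutting
#' very close to 1 instead merges anticorrelated modules and chains
#' background genes.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size Minimum genes per module (default 30, `>= 2`).
#' @param cut_height Static cut height on `1 - TOM` (default 0.9).
#' @return Tibble with `gene_id` and `module`, one row per input gene.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.9) {
  if (min_module_size < 2) abort("`min_module_size` must be >= 2.")
  genes <- rownames(tom)
  if (is.null(genes)) abort("TOM matrix must have gene rownames.")
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # order surviving clusters by descending size, ties by original label
  big <- big[order(-as.integer(sizes[big]), as.integer(big))]
  labels <- stats::setNames(rep("grey", length(cl)), genes)
  for (i in seq_along(big)) {
    name <- if (i <= length(wgcna_colors)) wgcna_colors[i] else paste0("module_", i)
    labels[cl == as.integer(big[i])] <- name
  }
  tibble(gene_id = genes, module = unname(labels))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene standardised (z-scored) expression submatrix: one value per
#' sample, scaled to unit variance, with the sign fixed so that the mean
#' correlation with member genes is non-negative. The proportion of
#' module variance explained by the eigengene is reported. Grey
#' (unassigned) genes get no eigengene.
#'
#' @inheritParams correlation_matrix
#' @param modules Module assignment tibble from [detect_modules()].
#' @return Tibble of class `module_eigengenes`: columns `module`,
#'   `variance_explained`, then one numeric column per sample.
#' @export
module_eigengenes <- function(expr, modules) {
  m <- as_expr_matrix(expr, "expr")
  mods <- setdiff(unique(modules$module), "grey")
  if (length(mods) == 0) abort("No non-grey modules to summarise.")
  rows <- purrr::map(mods, function(mod) {
    genes <- modules$gene_id[modules$module == mod]
    genes <- intersect(genes, rownames(m))
    if (length(genes) < 2) {
      abort(sprintf("Module '%s' has fewer than 2 genes with expression data.", mod))
    }
    x <- m[genes, , drop = FALSE]
    xs <- t(scale(t(x)))          # z-score each gene across samples
    if (anyNA(xs)) abort(sprintf("Module '%s' contains a constant gene.", mod))
    sv <- svd(xs)
    me <- sv$v[, 1]
    me <- me / stats::sd(me)
    mean_cor <- mean(apply(xs, 1, function(row) stats::cor(row, me)))
    if (mean_cor < 0) me <- -me
    varexp <- sv$d[1]^2 / sum(sv$d^2)
    out <- tibble(module = mod, variance_explained = varexp)
    me_row <- as.data.frame(as.list(stats::setNames(me, colnames(m))),
                            check.names = FALSE)
    dplyr::bind_cols(out, me_row)
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("module_eigengenes", class(res))
  res
}

# Extract the module x sample ME matrix from a module_eigengenes tibble.
me_matrix <- function(me) {
  samples <- setdiff(names(me), c("module", "variance_explained"))
  m <- as.matrix(me[samples])
  rownames(m) <- me$module
  m
}

#' Module-trait correlation
#'
#' Developmental stages are one-hot encoded (one indicator column per
#' stage) and each module eigengene is correlated against each indicator.
#' The p-value is the two-sided test of `r = 0` from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant indicators (a stage with all or no samples) give missing
#' values.
#'
#' @param me `module_eigengenes` tibble.
#' @param samples Sample table with `sample_id` and `stage`; sample ids
#'   must cover the eigengene columns.
#' @return Tibble of class `module_trait` with `module`, `stage`, `r`,
#'   `p_value`.
#' @export
module_trait_correlation <- function(me, samples) {
  mat <- me_matrix(me)
  if (ncol(mat) < 3) abort("At least 3 samples are required.")
  if (!all(colnames(mat) %in% samples$sample_id)) {
    abort("Sample table does not cover every eigengene sample.")
  }
  stage <- samples$stage[match(colnames(mat), samples$sample_id)]
  stages <- if (is.factor(samples$stage)) levels(samples$stage) else unique(stage)
  n <- ncol(mat)
  grid <- tidyr::expand_grid(module = rownames(mat), stage = stages)
  rows <- purrr::map2(grid$module, grid$stage, function(mod, st) {
    ind <- as.numeric(stage == st)
    if (stats::sd(ind) == 0) {
      return(tibble(module = mod, stage = st, r = NA_real_, p_value = NA_real_))
    }
    r <- stats::cor(mat[mod, ], ind)
    r2 <- min(r^2, 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    tibble(module = mod, stage = st, r = r, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "stages") <- stages
  class(out) <- c("module_trait", class(out))
  out
}
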