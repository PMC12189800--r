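# Co-expression network construction, module detection, eigengenes,
# module-trait correlation.

test_that("correlation matrix handles duplicates, negations and constants", {
  base <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m <- rbind(base, dup = base["g1", ], neg = -base["g2", ])
  r <- correlation_matrix(m)
  expect_equal(r["g1", "dup"], 1)
  expect_equal(r["g2", "neg"], -1)
  expect_true(isSymmetric(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
  mc <- rbind(m, flat = rep(3, 10))
  expect_error(correlation_matrix(mc), "flat")
  expect_warning(r2 <- correlation_matrix(mc, drop_constant = TRUE), "constant")
  expect_false("flat" %in% rownames(r2))
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("independent genes have correlations centred at zero", {
  withr::with_seed(7, {
    m <- matrix(rnorm(200 * 24), 200, 24,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:24)))
  })
  r <- correlation_matrix(m)
  pair_r <- r[cbind(seq(1, 199, 2), seq(2, 200, 2))]  # 100 disjoint pairs
  expect_lt(abs(mean(pair_r)), 0.1)
})

test_that("soft-threshold adjacency follows |r|^beta", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacency(r, 8)["a", "b"], 0.5^8)   # 0.00390625
  expect_equal(adjacency(r, 1)["a", "b"], 0.5)
  rneg <- r; rneg["a", "b"] <- rneg["b", "a"] <- -1
  expect_equal(adjacency(rneg, 7)["a", "b"], 1)
  expect_equal(diag(adjacency(r, 8)), c(a = 1, b = 1))
  expect_error(adjacency(r, 0.5), ">= 1")
})

test_that("soft-threshold report has monotone connectivity and picks reproducibly", {
  sim <- simulate_expression(expression_sim_config(
    n_modules = 2, genes_per_module = 40, n_background_genes = 120,
    samples_per_stage = 8, seed = 2))
  expr <- log_cpm(sim$counts)
  cands <- c(1, 2, 4, 6, 8, 10, 12)
  rep1 <- suppressWarnings(pick_soft_threshold(expr, candidates = cands))
  expect_true(all(diff(rep1$mean_connectivity) <= 1e-12))
  rep2 <- suppressWarnings(pick_soft_threshold(expr, candidates = cands))
  expect_identical(attr(rep1, "chosen_beta"), attr(rep2, "chosen_beta"))
  expect_true(attr(rep1, "chosen_beta") %in% rep1$beta)

  # all-independent genes: connectivities near zero and no moderate power
  # reaches the fit threshold, so the fallback warning path is taken
  withr::with_seed(3, {
    nullm <- matrix(rnorm(60 * 20), 60, 20,
                    dimnames = list(paste0("g", 1:60), paste0("s", 1:20)))
  })
  expect_warning(repn <- pick_soft_threshold(nullm, candidates = c(2, 6, 10)),
                 "best fit|undefined")
  expect_lt(repn$mean_connectivity[repn$beta == 10], 1)
})

test_that("TOM matches its closed form on the path fixture", {
  # a12 = a13 = 1, a23 = 0
  a <- matrix(c(1, 1, 1,
                1, 1, 0,
                1, 0, 1), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  tom <- tom_similarity(a)
  expect_equal(tom["g1", "g2"], 1)       # (0 + 1) / (1 + 1 - 1)
  expect_equal(tom["g2", "g3"], 0.5)     # (1 + 0) / (1 + 1 - 0)
  expect_equal(diag(tom), c(g1 = 1, g2 = 1, g3 = 1))
  # all-zero off-diagonal adjacency -> zero off-diagonal TOM
  z <- diag(3); dimnames(z) <- dimnames(a)
  expect_equal(tom_similarity(z)[upper.tri(z)], c(0, 0, 0))
  # symmetry and range on a random adjacency
  withr::with_seed(4, {
    r <- cor(matrix(rnorm(20 * 12), 12, 20))
    dimnames(r) <- list(paste0("g", 1:20), paste0("g", 1:20))
  })
  t2 <- tom_similarity(adjacency(r, 6))
  expect_true(isSymmetric(t2))
  expect_true(all(t2 >= 0 & t2 <= 1 + 1e-12))
})

test_that("module detection separates planted blocks and greys out noise", {
  # two blocks of mutually identical genes, zero cross-correlation -> 2 modules
  withr::with_seed(5, {
    p1 <- rnorm(12); p2 <- rnorm(12)
    p2 <- residuals(lm(p2 ~ p1))  # orthogonalise
    m <- rbind(matrix(rep(p1, each = 4), 4, byrow = FALSE),
               matrix(rep(p2, each = 4), 4, byrow = FALSE))
  })
  m <- m + withr::with_seed(55, matrix(rnorm(length(m), sd = 1e-3), nrow(m)))  # break exact ties
  dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:12))
  tom <- tom_similarity(adjacency(correlation_matrix(m), 6))
  mods <- detect_modules(tom, min_module_size = 2, cut_height = 0.9)
  expect_equal(length(setdiff(unique(mods$module), "grey")), 2)
  expect_equal(length(unique(mods$module[1:4])), 1)
  expect_equal(length(unique(mods$module[5:8])), 1)
  # largest module gets the first conventional colour
  expect_true("turquoise" %in% mods$module)

  # independent genes end up overwhelmingly grey under defaults
  withr::with_seed(6, {
    nullm <- matrix(rnorm(150 * 24), 150, 24,
                    dimnames = list(paste0("g", 1:150), paste0("s", 1:24)))
  })
  tomn <- tom_similarity(adjacency(correlation_matrix(nullm), 8))
  modn <- detect_modules(tomn)
  expect_gte(mean(modn$module == "grey"), 0.9)

  # min_module_size larger than the gene count greys everything
  all_grey <- detect_modules(tomn, min_module_size = 151)
  expect_true(all(all_grey$module == "grey"))
  expect_error(detect_modules(tomn, min_module_size = 1), ">= 2")
})

test_that("module detection is invariant to gene input order up to labels", {
  sim <- simulate_expression(expression_sim_config(
    n_modules = 2, genes_per_module = 35, n_background_genes = 60,
    samples_per_stage = 8, seed = 8))
  expr <- log_cpm(sim$counts)
  tom <- tom_similarity(adjacency(correlation_matrix(expr, drop_constant = TRUE), 8))
  mods <- detect_modules(tom)
  perm <- withr::with_seed(1, sample(nrow(tom)))
  mods_p <- detect_modules(tom[perm, perm])
  joined <- merge(mods, mods_p, by = "gene_id")
  tab <- table(joined$module.x, joined$module.y)
  # permutation matrix: each label maps to exactly one label
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module eigengenes summarise their module and fix the sign", {
  withr::with_seed(9, profile <- rnorm(10))
  m <- matrix(rep(profile, each = 5), 5, byrow = FALSE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m <- m * runif(5, 0.5, 2)  # scaled copies of one profile
  mods <- tibble::tibble(gene_id = rownames(m), module = "turquoise")
  me <- module_eigengenes(m, mods)
  expect_equal(me$variance_explained, 1.0, tolerance = 1e-10)
  mevec <- as.numeric(as.matrix(me[-(1:2)]))
  expect_equal(mevec, as.numeric(scale(profile)), tolerance = 1e-8)
  # appending the negation of every member leaves |ME| unchanged
  m2 <- rbind(m, -m)
  rownames(m2) <- c(rownames(m), paste0("n", 1:5))
  mods2 <- tibble::tibble(gene_id = rownames(m2), module = "turquoise")
  me2 <- module_eigengenes(m2, mods2)
  expect_equal(abs(as.numeric(as.matrix(me2[-(1:2)]))), abs(mevec),
               tolerance = 1e-8)
  # sign rule: mean correlation with members is non-negative
  expect_gte(mean(apply(t(scale(t(m))), 1, cor, y = mevec)), 0)
  expect_error(module_eigengenes(m, tibble::tibble(gene_id = "g1", module = "x")),
               "fewer than 2")
})

test_that("planted module eigengene is recovered with high fidelity", {
  sim <- simulate_expression(expression_sim_config(seed = 1))
  expr <- log_cpm(sim$counts)
  tom <- tom_similarity(adjacency(correlation_matrix(expr, drop_constant = TRUE), 8))
  mods <- detect_modules(tom)
  me <- module_eigengenes(expr, mods)
  truth <- sim$truth$gene_modules
  for (planted in rownames(sim$truth$eigengenes)) {
    genes <- truth$gene_id[truth$module == planted]
    det <- names(which.max(table(mods$module[mods$gene_id %in% genes])))
    expect_false(det == "grey")
    mevec <- as.numeric(as.matrix(me[me$module == det, -(1:2)]))
    expect_gte(abs(cor(mevec, sim$truth$eigengenes[planted, ])), 0.9)
  }
})

test_that("module-stage correlation matches the t-distribution closed form", {
  # construct an eigengene with exact sample correlation 0.9 to a stage
  # indicator over n = 12 samples (6 + 6 design)
  samples <- tibble::tibble(sample_id = paste0("s", 1:12),
                            stage = factor(rep(c("early", "late"), each = 6),
                                           levels = c("early", "late")))
  ind <- as.numeric(samples$stage == "late")
  zx <- as.numeric(scale(ind))
  withr::with_seed(10, e <- rnorm(12))
  ze <- as.numeric(scale(residuals(lm(e ~ ind))))
  mevec <- 0.9 * zx + sqrt(1 - 0.9^2) * ze
  me <- tibble::tibble(module = "turquoise", variance_explained = 1)
  me <- dplyr::bind_cols(me, tibble::as_tibble(as.list(
    stats::setNames(mevec, samples$sample_id))))
  class(me) <- c("module_eigengenes", class(me))
  mt <- module_trait_correlation(me, samples)
  late <- mt[mt$stage == "late", ]
  expect_equal(late$r, 0.9, tolerance = 1e-10)
  # independently derived: t = 0.9 * sqrt(10 / 0.19) = 6.529..., p ~ 6.6e-5
  expect_equal(late$p_value, 6.6e-5, tolerance = 0.02)
  early <- mt[mt$stage == "early", ]
  expect_equal(early$r, -0.9, tolerance = 1e-10)

  # ME identical to an indicator -> r = 1; orthogonal -> r ~ 0, p ~ 1
  me_ind <- me
  me_ind[1, samples$sample_id] <- as.list(zx)
  mt2 <- module_trait_correlation(me_ind, samples)
  expect_equal(mt2$r[mt2$stage == "late"], 1, tolerance = 1e-10)
  me_orth <- me
  me_orth[1, samples$sample_id] <- as.list(ze)
  mt3 <- module_trait_correlation(me_orth, samples)
  expect_equal(mt3$r[mt3$stage == "late"], 0, tolerance = 1e-10)
  expect_equal(mt3$p_value[mt3$stage == "late"], 1, tolerance = 1e-8)
})

test_that("a planted stage-rising module correlates most with the right stage", {
  sim <- simulate_expression(expression_sim_config(seed = 2))
  expr <- log_cpm(sim$counts)
  tom <- tom_similarity(adjacency(correlation_matrix(expr, drop_constant = TRUE), 8))
  mods <- detect_modules(tom)
  me <- module_eigengenes(expr, mods)
  mt <- module_trait_correlation(me, sim$samples)
  truth <- sim$truth$gene_modules
  rising_genes <- truth$gene_id[truth$module == "M1"]   # trend -1, 0, 1
  det <- names(which.max(table(mods$module[mods$gene_id %in% rising_genes])))
  sub <- mt[mt$module == det, ]
  extreme <- sub$stage[which.max(abs(sub$r))]
  expect_true(extreme %in% c("8cell", "32cell"))
})
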