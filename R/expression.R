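#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is a header row of sample ids, a first column named
#' `gene_id` (or any non-numeric first column), and one row per gene with
#' non-negative numeric counts. Reading is strict: duplicated gene ids,
#' non-numeric cells and ragged rows are errors that name the offending
#' line, because silently coerced counts corrupt every downstream network.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample.
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path) {
  raw <- readLines(path)
  if (length(raw) < 2) abort("Count matrix file must have a header and at least one gene row.")
  fields <- strsplit(raw, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged) > 0) {
    abort(sprintf("Ragged row in %s: line %d has %d fields, header has %d.",
                  path, ragged[1], lengths(fields)[ragged[1]], width))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    line <- which(ids == dup)[2] + 1L
    abort(sprintf("Duplicate gene id '%s' in %s (line %d).", dup, path, line))
  }
  counts <- df[-1]
  for (j in seq_along(counts)) {
    v <- suppressWarnings(as.numeric(counts[[j]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      abort(sprintf("Non-numeric cell '%s' in %s (line %d, column '%s').",
                    counts[[j]][row], path, row + 1L, names(counts)[j]))
    }
    counts[[j]] <- v
  }
  out <- tibble::as_tibble(counts)
  out <- dplyr::bind_cols(tibble(gene_id = ids), out)
  out
}

#' Write a count matrix to TSV
#'
#' @param x Count matrix as returned by [read_count_matrix()] (tibble with
#'   `gene_id`) or a matrix with gene rownames.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  if (is.matrix(x)) x <- expr_as_tibble(x)
  readr::write_tsv(x, path)
  invisible(x)
}

#' Log counts-per-million transform
#'
#' Library-size normalisation followed by a log transform:
#' `log2(pseudocount + count / library_size * 1e6)`. This is the default
#' variance-stabilising step upstream of co-expression network construction;
#' correlation networks built on raw counts are dominated by sequencing
#' depth. Pass raw counts through untouched with `use_raw_counts = TRUE` in
#' the pipeline when literal replication of a counts-based analysis is
#' wanted.
#'
#' @param counts Count matrix (tibble with `gene_id` or matrix).
#' @param pseudocount Offset added inside the log; default 1 so zero counts
#'   map to 0.
#' @return Same shape as the input, with counts replaced by log2-CPM values.
#' @export
log_cpm <- function(counts, pseudocount = 1) {
  m <- as_expr_matrix(counts, "counts")
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(sprintf("Samples with zero library size: %s",
                  paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  out <- log2(pseudocount + sweep(m, 2, lib, "/") * 1e6)
  restore_expr_shape(out, counts)
}

#' Per-gene median absolute deviation
#'
#' Raw MAD, `median(|x - median(x)|)` per gene, without the Gaussian
#' consistency constant: it is a ranking statistic here, not a scale
#' estimate.
#'
#' @param x Expression matrix (tibble with `gene_id` or matrix).
#' @return Tibble with `gene_id` and `mad`, in input gene order.
#' @export
gene_mad <- function(x) {
  m <- as_expr_matrix(x, "x")
  tibble(gene_id = rownames(m),
         mad = unname(apply(m, 1, stats::mad, constant = 1)))
}

#' Select the k most variable genes by MAD
#'
#' Ranks genes by raw median absolute deviation (descending) and keeps the
#' top `k`; MAD ties are broken lexicographically by gene id so the
#' selection is reproducible. Constant genes (MAD 0) rank last.
#'
#' @param x Expression matrix (tibble with `gene_id` or matrix).
#' @param k Number of genes to keep; must not exceed the number of genes.
#' @return The selected rows of `x`, ordered by decreasing MAD.
#' @export
mad_select_top_k <- function(x, k) {
  m <- as_expr_matrix(x, "x")
  k <- check_count(k, "k", min = 1L)
  if (k > nrow(m)) {
    abort(sprintf("k = %d exceeds the number of genes (%d).", k, nrow(m)))
  }
  mads <- apply(m, 1, stats::mad, constant = 1)
  ord <- order(-mads, rownames(m))
  keep <- m[ord[seq_len(k)], , drop = FALSE]
  restore_expr_shape(keep, x)
}

deg_aliases <- c(
  gene_id = "gene_id", gene = "gene_id",
  log2_fold_change = "log2_fold_change", log2FoldChange = "log2_fold_change",
  log2fc = "log2_fold_change", lfc = "log2_fold_change",
  p_value = "p_value", pvalue = "p_value", p = "p_value",
  p_adjusted = "p_adjusted", padj = "p_adjusted", p.adj = "p_adjusted",
  p_adj = "p_adjusted"
)

standardise_deg_table <- function(table) {
  nm <- names(table)
  canon <- unname(deg_aliases[nm])
  names(table)[!is.na(canon)] <- canon[!is.na(canon)]
  required <- c("gene_id", "log2_fold_change", "p_adjusted")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(sprintf("DE table is missing required columns: %s",
                  paste(missing, collapse = ", ")))
  }
  as_tibble(table)
}

#' Filter a differential-expression table to significant genes
#'
#' Applies the conventional DEG definition: `|log2FC| > lfc_cut` and
#' adjusted p below `padj_cut`, both strict inequalities, so boundary genes
#' (e.g. log2FC exactly 1) are excluded. Rows with missing adjusted p
#' (as emitted by independent-filtering DE tools) are dropped. Column names
#' follow either this package's convention (`log2_fold_change`,
#' `p_adjusted`) or the common `log2FoldChange`/`pvalue`/`padj` spelling.
#'
#' @param table Data frame with gene id, log2 fold change and adjusted p.
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param padj_cut Adjusted-p threshold (default 0.05).
#' @return Tibble of retained rows with standardised column names.
#' @export
filter_deg_table <- function(table, lfc_cut = 1, padj_cut = 0.05) {
  table <- standardise_deg_table(table)
  dplyr::filter(table,
                !is.na(.data$p_adjusted),
                abs(.data$log2_fold_change) > lfc_cut,
                .data$p_adjusted < padj_cut)
}

#' Overlap structure of several DEG sets
#'
#' Computes the exclusive (Venn-style) membership regions of two or more
#' gene sets, typically DEG lists from different stage contrasts. Each gene
#' is assigned to exactly one region, the combination of contrasts that
#' contain it; the region covering all contrasts is the full intersection.
#'
#' @param tables Named list of filtered DEG tables (anything with a
#'   `gene_id`/`gene` column) or of character vectors of gene ids.
#' @return Tibble with one row per non-empty region: `contrasts` (names
#'   joined by `&`), `degree` (number of contrasts in the region), `n_genes`
#'   and a `genes` list-column.
#' @export
contrast_overlap <- function(tables) {
  if (!is.list(tables) || length(tables) < 2) {
    abort("`tables` must be a list of at least two DEG tables or gene sets.")
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("set", seq_along(tables))
  }
  sets <- purrr::map(tables, function(t) {
    if (is.character(t)) return(unique(t))
    nm <- names(t)
    col <- c("gene_id", "gene")[c("gene_id", "gene") %in% nm][1]
    if (is.na(col)) abort("Each table needs a `gene_id` (or `gene`) column.")
    unique(as.character(t[[col]]))
  })
  genes <- sort(unique(unlist(sets)))
  if (length(genes) == 0) {
    return(tibble(contrasts = character(), degree = integer(),
                  n_genes = integer(), genes = list()))
  }
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(sets)))
  sig <- apply(member, 1, function(r) paste(colnames(member)[r], collapse = "&"))
  split_genes <- split(genes, sig)
  out <- tibble(
    contrasts = names(split_genes),
    degree = unname(lengths(strsplit(names(split_genes), "&", fixed = TRUE))),
    n_genes = unname(lengths(split_genes)),
    genes = unname(split_genes)
  )
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$contrasts)
}
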