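# Internal helpers shared across modules.

# Coerce a counts/expression object to a numeric matrix with gene rownames.
# Accepts a matrix (rownames = genes) or a data frame whose first column is
# `gene_id` (any non-numeric first column is treated as the id column).
as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(sprintf("`%s` matrix must have gene ids as rownames.", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a matrix or data frame, not %s.", arg, class(x)[1]))
  }
  id_col <- if ("gene_id" %in% names(x)) "gene_id" else names(x)[1]
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate gene ids: %s", paste(head(dups, 5), collapse = ", ")))
  }
  num <- x[setdiff(names(x), id_col)]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric sample columns: %s", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  m
}

# Inverse of as_expr_matrix: matrix -> tibble with leading gene_id column.
expr_as_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "gene_id")
}

# Keep the tabular flavour of the input: if the user passed a data frame,
# give one back; matrices stay matrices.
restore_expr_shape <- function(m, template) {
  if (is.data.frame(template)) expr_as_tibble(m) else m
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  as.numeric(x)
}
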