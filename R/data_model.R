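#' Construct and validate an expression matrix
#'
#' An expression matrix holds log-scale expression values for one species,
#' genes in rows and samples in columns. It is represented as a plain numeric
#' matrix with unique gene identifiers as row names and unique sample
#' identifiers as column names; all entries must be finite.
#'
#' @param values numeric matrix (genes x samples).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(gene_ids) && nrow(values) == 0L) gene_ids <- character(0)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of 'gene_ids' must equal the number of rows")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of 'sample_ids' must equal the number of columns")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite (no NA/NaN/Inf)")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Construct and validate a one-to-one ortholog map
#'
#' The map pairs gene identifiers across the two species. The model is
#' defined on one-to-one ortholog pairs, so any identifier may appear at most
#' once in its column; many-to-many relations are rejected at load time.
#'
#' @param id1,id2 character vectors of equal length: species-1 and species-2
#'   gene identifiers of each ortholog pair.
#' @return a data frame with columns `id1`, `id2` and class `ortholog_map`.
#' @export
ortholog_map <- function(id1, id2) {
  id1 <- as.character(id1)
  id2 <- as.character(id2)
  if (length(id1) != length(id2)) stop("'id1' and 'id2' differ in length")
  if (anyDuplicated(id1)) {
    stop("duplicate species-1 id in ortholog map: ",
         id1[duplicated(id1)][1L])
  }
  if (anyDuplicated(id2)) {
    stop("duplicate species-2 id in ortholog map: ",
         id2[duplicated(id2)][1L])
  }
  structure(data.frame(id1 = id1, id2 = id2, stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' Pair two expression matrices through an ortholog map
#'
#' Aligns the profiles of mapped ortholog pairs (in map order) and retains
#' every unmapped gene of either species as an unpaired profile: genes
#' without orthologues still participate in the clustering through their own
#' species' mixture.
#'
#' @param expr1,expr2 expression matrices for species 1 and 2 (see
#'   [expression_matrix()]).
#' @param map an [ortholog_map()].
#' @param on_missing what to do when a map id is absent from its matrix:
#'   `"error"` (default) rejects; `"skip"` drops the pair with a warning.
#' @return an object of class `paired_dataset`: a list with the paired
#'   profile matrices `x1` (pairs x d1) and `x2` (pairs x d2), the pair
#'   identifiers `pair_id1`/`pair_id2`, the unpaired profile matrices
#'   `u1`/`u2`, and the per-species sample counts `d1`, `d2`.
#' @export
build_paired_dataset <- function(expr1, expr2, map,
                                 on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  expr1 <- expression_matrix(expr1)
  expr2 <- expression_matrix(expr2)
  if (!inherits(map, "ortholog_map")) map <- ortholog_map(map[[1L]], map[[2L]])
  in1 <- map$id1 %in% rownames(expr1)
  in2 <- map$id2 %in% rownames(expr2)
  ok <- in1 & in2
  if (!all(ok)) {
    missing_ids <- c(map$id1[!in1], map$id2[!in2])
    if (on_missing == "error") {
      stop("ortholog map ids absent from expression matrix: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    warning(sum(!ok), " map entries skipped (ids absent from a matrix)")
    map <- map[ok, , drop = FALSE]
  }
  x1 <- expr1[map$id1, , drop = FALSE]
  x2 <- expr2[map$id2, , drop = FALSE]
  u1 <- expr1[setdiff(rownames(expr1), map$id1), , drop = FALSE]
  u2 <- expr2[setdiff(rownames(expr2), map$id2), , drop = FALSE]
  structure(list(
    x1 = x1, x2 = x2,
    pair_id1 = rownames(x1), pair_id2 = rownames(x2),
    u1 = u1, u2 = u2,
    d1 = ncol(expr1), d2 = ncol(expr2)
  ), class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("paired_dataset:", nrow(x$x1), "ortholog pairs;",
      nrow(x$u1), "unpaired species-1 genes;",
      nrow(x$u2), "unpaired species-2 genes;",
      "d1 =", x$d1, ", d2 =", x$d2, "\n")
  invisible(x)
}

n_genes_total <- function(data) {
  2L * nrow(data$x1) + nrow(data$u1) + nrow(data$u2)
}

#' Per-gene standardization of expression profiles
#'
#' Optional per-gene scaling applied before clustering. `"none"` returns the
#' input unchanged, `"center"` subtracts each gene's mean, `"zscore"`
#' additionally divides by the population standard deviation (denominator
#' `n`, not `n - 1`).
#'
#' @param expr an expression matrix.
#' @param mode one of `"none"`, `"center"`, `"zscore"`.
#' @return the transformed expression matrix.
#' @export
standardize_profiles <- function(expr, mode = c("none", "center", "zscore")) {
  mode <- match.arg(mode)
  expr <- expression_matrix(expr)
  if (mode == "none") return(expr)
  mu <- rowMeans(expr)
  out <- expr - mu
  if (mode == "zscore") {
    sd_pop <- sqrt(rowMeans(out^2))
    if (any(sd_pop == 0)) {
      stop("zero-variance gene(s) under zscore standardization: ",
           paste(utils::head(rownames(expr)[sd_pop == 0], 5L),
                 collapse = ", "))
    }
    out <- out / sd_pop
  }
  out
}
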