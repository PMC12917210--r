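#' Sparse count matrix with sample labels
#'
#' Container for a genes x cells matrix of non-negative integer UMI counts,
#' together with gene display names and a per-barcode sample label. This is
#' the object every downstream stage consumes; barcodes must be unique and
#' every barcode must carry a sample label.
#'
#' @param m A `dgCMatrix` (genes x cells) of non-negative integer counts with
#'   rownames (gene ids) and colnames (barcodes).
#' @param gene_name Character vector of display names, parallel to rows of
#'   `m`. Defaults to the rownames.
#' @param sample Character vector of sample labels, parallel to columns of
#'   `m` (recycled if length 1).
#' @return An object of class `count_matrix` with fields `m`, `gene_name`,
#'   `sample`.
#' @export
count_matrix <- function(m, gene_name = rownames(m), sample) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix needs gene ids as rownames and barcodes as colnames")
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate barcodes in count matrix: ",
         paste(utils::head(colnames(m)[duplicated(colnames(m))], 3), collapse = ", "))
  }
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x)))) {
    stop("counts must be non-negative integers")
  }
  if (length(sample) == 1L) sample <- rep(sample, ncol(m))
  if (length(sample) != ncol(m)) stop("one sample label per barcode required")
  stopifnot(length(gene_name) == nrow(m))
  structure(
    list(m = m, gene_name = as.character(gene_name),
         sample = stats::setNames(as.character(sample), colnames(m))),
    class = "count_matrix"
  )
}

#' Log-normalized expression matrix
#'
#' Same axes as the source [count_matrix()]; values are log-normalized
#' non-negative reals with the sparsity pattern of the counts.
#' @param m sparse genes x cells matrix of normalized values
#' @param gene_name,sample as in [count_matrix()]
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(m, gene_name = rownames(m), sample) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (length(sample) == 1L) sample <- rep(sample, ncol(m))
  structure(
    list(m = m, gene_name = as.character(gene_name),
         sample = stats::setNames(as.character(sample), colnames(m))),
    class = "expr_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$m)
#' @export
dim.expr_matrix <- function(x) dim(x$m)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d samples (%s)\n",
              nrow(x$m), ncol(x$m), length(unique(x$sample)),
              paste(unique(x$sample), collapse = ", ")))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (log-normalized): %d genes x %d cells\n",
              nrow(x$m), ncol(x$m)))
  invisible(x)
}

#' Subset a count or expression matrix by cells
#'
#' @param x a `count_matrix` or `expr_matrix`
#' @param barcodes character vector (or logical/integer index) of cells
#' @return object of the same class restricted to those cells, order given by
#'   `barcodes`.
#' @export
subset_cells <- function(x, barcodes) {
  stopifnot(inherits(x, c("count_matrix", "expr_matrix")))
  m <- x$m[, barcodes, drop = FALSE]
  out <- list(m = m, gene_name = x$gene_name, sample = x$sample[colnames(m)])
  class(out) <- class(x)
  out
}

# run code with a private, restorable RNG state; `seed` fully determines it
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
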