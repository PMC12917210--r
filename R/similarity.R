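#' Cluster-by-sample composition table
#'
#' Counts of cells per cluster and sample, with per-sample column
#' percentages. Full-precision percentages are retained; a display copy
#' rounded to two decimals (plus `Total` margins, the total percentage being
#' the sum of the rounded entries, matching tabulation practice) is
#' included.
#'
#' @param labels cluster labels (a `cluster_labels` or named vector).
#' @param sample_of_barcode named character vector: sample per barcode.
#' @return list of class `proportion_table`: `counts` (cluster x sample
#'   matrix with Total margins), `pct` (full precision, clusters x samples),
#'   `pct_display` (rounded, with Total row).
#' @export
cluster_proportions <- function(labels, sample_of_barcode) {
  if (inherits(labels, "cluster_labels")) labels <- labels$labels
  cells <- names(labels)
  if (is.null(cells)) stop("labels must be named by barcode")
  samp <- sample_of_barcode[cells]
  if (anyNA(samp)) stop("every barcode needs a sample")
  tab <- table(cluster = labels, sample = samp)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  disp <- round(pct, 2)
  counts_m <- rbind(cbind(counts, Total = rowSums(counts)),
                    Total = c(colSums(counts), sum(counts)))
  pct_tot <- round(rowSums(counts) / sum(counts) * 100, 2)
  disp_m <- rbind(cbind(disp, Total = pct_tot),
                  Total = colSums(rbind(cbind(disp, Total = pct_tot))))
  structure(list(counts = counts_m, pct = pct, pct_display = disp_m),
            class = "proportion_table")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom (`p = 0` at `|rho| = 1`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `rho`, `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Per-sample average expression profile
#'
#' Arithmetic mean of log-normalized expression of every gene within each
#' sample.
#'
#' @param expr an [expr_matrix()].
#' @return numeric matrix genes x samples.
#' @export
sample_expression_profile <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  samples <- unique(expr$sample)
  prof <- vapply(samples, function(s) {
    idx <- which(expr$sample == s)
    if (!length(idx)) stop("empty sample: ", s)
    Matrix::rowMeans(expr$m[, idx, drop = FALSE])
  }, numeric(nrow(expr$m)))
  colnames(prof) <- samples
  prof
}

#' Pairwise Spearman correlation matrix of sample columns
#'
#' Accepts a `proportion_table` (its full-precision percentage columns are
#' correlated), a profile matrix from [sample_expression_profile()], or any
#' numeric matrix with one column per sample.
#'
#' @param x table or matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  m <- if (inherits(x, "proportion_table")) x$pct else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two samples")
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- spearman_cor(m[, i], m[, j])$rho
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}
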