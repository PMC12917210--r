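#' Pipeline thresholds
#'
#' The fixed thresholds of the analysis, overridable individually. Defaults:
#' cells kept with 200--3,000 detected genes and at most 15% mitochondrial
#' counts; normalization to 10,000 counts per cell (natural log); 2,000
#' highly variable genes; 50 computed principal components with the number
#' retained chosen to reach 90% of their variance; Leiden resolutions 0.1 to
#' 0.8 in steps of 0.1; annotation markers require detection in at least 25%
#' of in-group cells, average log2 fold change of at least 4 and adjusted
#' p at most 0.05; rare-cell z threshold 1.96 (central 95% normal coverage);
#' subcluster-unique markers require a three-fold mean-expression margin with
#' a 0.25 log-expression floor; enrichment records kept at adjusted p at most
#' 0.1; scaled values clipped at +10.
#'
#' @param ... named overrides of any default listed above.
#' @return list of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(...) {
  t <- list(
    min_genes = 200, max_genes = 3000, max_pct_mito = 15.0,
    n_hvgs = 2000, n_pcs_computed = 50, variance_fraction = 0.90,
    resolutions = seq(0.1, 0.8, by = 0.1),
    normalize_scale = 10000,
    anno_min_pct = 0.25, anno_min_log2fc = 4.0, anno_max_padj = 0.05,
    rare_z = 1.96, unique_fold = 3.0, unique_floor = 0.25,
    gsea_max_padj = 0.1, scale_clip = 10,
    k_neighbors = 20, snn_prune = 1 / 15)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(t))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    t[names(over)] <- over
  }
  stopifnot(t$min_genes < t$max_genes, t$max_pct_mito > 0,
            !is.unsorted(t$resolutions))
  structure(t, class = "pipeline_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell: the number of detected genes, total molecules, and the
#' percentage of counts attributed to mitochondrial genes (0 for empty
#' cells).
#'
#' @param counts a [count_matrix()].
#' @param mito either a prefix string matched against gene names/ids
#'   (default `"MT-"`) or a character vector of explicit gene ids.
#' @return data.frame (one row per cell): barcode, sample, n_genes_detected,
#'   n_molecules, pct_mito.
#' @export
compute_cell_qc <- function(counts, mito = "MT-") {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$m
  mito_rows <- if (length(mito) == 1L && !mito %in% rownames(m)) {
    which(startsWith(rownames(m), mito) | startsWith(counts$gene_name, mito))
  } else {
    which(rownames(m) %in% mito)
  }
  total <- Matrix::colSums(m)
  mito_counts <- if (length(mito_rows)) {
    Matrix::colSums(m[mito_rows, , drop = FALSE])
  } else rep(0, ncol(m))
  pct <- ifelse(total > 0, 100 * mito_counts / total, 0)
  data.frame(barcode = colnames(m), sample = unname(counts$sample),
             n_genes_detected = Matrix::colSums(m > 0),
             n_molecules = unname(total), pct_mito = unname(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the cell-level quality filters
#'
#' Retains cells with `min_genes <= n_genes_detected <= max_genes` and
#' `pct_mito <= max_pct_mito` ("less than 200 / more than 3,000 / more than
#' 15%" read literally, so the boundaries themselves are kept). Cell order is
#' preserved; filtering is idempotent.
#'
#' @param counts a [count_matrix()].
#' @param qc the matching table from [compute_cell_qc()].
#' @param t a [pipeline_thresholds()].
#' @return the filtered [count_matrix()].
#' @export
filter_cells <- function(counts, qc, t = pipeline_thresholds()) {
  stopifnot(identical(qc$barcode, colnames(counts$m)))
  keep <- qc$n_genes_detected >= t$min_genes &
    qc$n_genes_detected <= t$max_genes &
    qc$pct_mito <= t$max_pct_mito
  if (!any(keep)) stop("empty after QC: no cells pass the filters")
  subset_cells(counts, which(keep))
}

#' Log-normalize counts
#'
#' `value = ln(1 + count * scale / cell_total)`; zero counts map to exactly
#' zero, so the sparsity pattern is preserved.
#'
#' @param counts a [count_matrix()] (post-QC: no zero-total cells).
#' @param scale scale factor (default 10,000).
#' @return an [expr_matrix()].
#' @export
lognormalize <- function(counts, scale = 10000) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$m
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(m)[total == 0], 3), collapse = ", "))
  }
  fac <- scale / total
  e <- m
  if (length(e@x)) {
    col_of <- rep.int(seq_len(ncol(m)), diff(m@p))
    e@x <- log1p(m@x * fac[col_of])
  }
  expr_matrix(e, gene_name = counts$gene_name, sample = counts$sample)
}

#' Select highly variable genes (vst-style)
#'
#' Ranks genes by their variance of standardized raw counts: a loess trend of
#' log10 variance on log10 mean is fitted across genes, counts are
#' standardized by the trend-expected standard deviation (clipped at
#' `sqrt(n_cells)`), and the variance of the standardized values is the
#' ranking statistic. Deterministic given the input; ties broken by gene id.
#'
#' @param counts a [count_matrix()] of raw counts.
#' @param n number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of the top `n` gene ids in rank order.
#' @export
select_hvgs <- function(counts, n = 2000, loess_span = 0.3) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$m
  if (n > nrow(m)) stop("n exceeds the number of genes")
  N <- ncol(m)
  mu <- Matrix::rowSums(m) / N
  ex2 <- Matrix::rowSums(m^2) / N
  v <- (ex2 - mu^2) * N / (N - 1)
  std_var <- numeric(nrow(m))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 10) {
    # trend-fit numerics warn on very small gene panels; the fit itself is fine
    fit <- suppressWarnings(stats::loess(log10(v[ok]) ~ log10(mu[ok]),
                                         span = loess_span, degree = 2))
    sd_e <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(N)
    tm <- methods::as(m[ok, , drop = FALSE], "TsparseMatrix")
    z_nz <- pmin((tm@x - mu[ok][tm@i + 1L]) / sd_e[tm@i + 1L], clip)
    s_nz <- rowsum(z_nz^2, tm@i, reorder = FALSE)
    s2 <- numeric(sum(ok))
    s2[unique(tm@i) + 1L] <- s_nz[, 1]
    nnz <- tabulate(tm@i + 1L, nbins = sum(ok))
    z0 <- pmax(-mu[ok] / sd_e, -clip)
    std_var[ok] <- (s2 + (N - nnz) * z0^2) / (N - 1)
  } else {
    std_var[ok] <- v[ok]
  }
  ord <- order(-std_var, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Center and scale selected genes
#'
#' Per-gene zero mean and unit variance over cells (sample standard
#' deviation, n-1 denominator; constant genes map to all zeros), with values
#' capped from above at `clip`.
#'
#' @param expr an [expr_matrix()].
#' @param genes gene ids to scale (typically the HVG list).
#' @param clip upper cap for scaled values (default 10).
#' @return list of class `scaled_matrix`: `mat` (dense genes x cells) and
#'   `hvg`.
#' @export
scale_center <- function(expr, genes, clip = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!length(genes)) stop("empty gene list")
  missing <- setdiff(genes, rownames(expr$m))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  x <- as.matrix(expr$m[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  x <- (x - mu) / ifelse(sd > 0, sd, 1)
  x[sd == 0, ] <- 0
  x[x > clip] <- clip
  structure(list(mat = x, hvg = genes, sample = expr$sample),
            class = "scaled_matrix")
}

#' Six-number summary of QC metrics
#'
#' Min, first quartile, median, mean, third quartile and max per QC metric,
#' overall or per group. Quartiles use linear interpolation (type 7).
#'
#' @param qc table from [compute_cell_qc()].
#' @param group optional vector of group labels (one per cell).
#' @return data.frame with columns group (if given), metric, min, q1, median,
#'   mean, q3, max.
#' @export
summarize_qc <- function(qc, group = NULL) {
  metrics <- c("n_molecules", "n_genes_detected", "pct_mito")
  one <- function(df, g) {
    do.call(rbind, lapply(metrics, function(mm) {
      v <- df[[mm]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group = g, metric = mm, min = min(v), q1 = q[1],
                 median = q[2], mean = mean(v), q3 = q[3], max = max(v),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(group)) {
    out <- one(qc, NA_character_)
    out$group <- NULL
    return(out)
  }
  stopifnot(length(group) == nrow(qc))
  out <- do.call(rbind, lapply(split(seq_len(nrow(qc)), group), function(i) {
    one(qc[i, , drop = FALSE], as.character(group[i[1]]))
  }))
  rownames(out) <- NULL
  out
}
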