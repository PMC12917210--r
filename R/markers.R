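#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location shift. For small tie-free problems
#' (`length(x) + length(y) <= 12`, no ties) the exact null distribution of U
#' is used; otherwise a tie-corrected normal approximation with continuity
#' correction. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y non-empty numeric vectors.
#' @return list: `statistic` (U for the `x` group) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= 12) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sig2 <= 0) return(list(statistic = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p = p)
}

#' Average log2 fold change between cell groups
#'
#' Computed on de-logged means with a pseudocount of one:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. Inputs are
#' log-normalized expression values.
#'
#' @param in_cells,out_cells numeric vectors of log-normalized expression.
#' @return the log2 fold change (antisymmetric under group swap).
#' @export
log2_fold_change <- function(in_cells, out_cells) {
  log2((mean(expm1(in_cells)) + 1) / (mean(expm1(out_cells)) + 1))
}

# genes x clusters matrices of group sums / detection counts
group_stats <- function(m, lab) {
  cl <- sort(unique(lab))
  ind <- Matrix::sparseMatrix(i = seq_along(lab), j = match(lab, cl), x = 1,
                              dims = c(length(lab), length(cl)),
                              dimnames = list(NULL, cl))
  em <- m; if (length(em@x)) em@x <- expm1(em@x)
  bin <- m; if (length(bin@x)) bin@x <- rep(1, length(bin@x))
  list(clusters = cl, n = as.vector(Matrix::colSums(ind)),
       expm1_sum = as.matrix(em %*% ind),
       det = as.matrix(bin %*% ind),
       logsum = as.matrix(m %*% ind))
}

#' One-vs-rest marker testing across all clusters
#'
#' For every cluster, every gene detected in at least `min_pct` of either the
#' in-group or the out-group and with `|log2FC| >= min_log2fc` is tested with
#' the Wilcoxon rank-sum test against all remaining cells. p-values are
#' Benjamini-Hochberg adjusted over the tests performed within each cluster.
#' Clusters with fewer than three cells are skipped with a warning.
#'
#' @param expr an [expr_matrix()] of log-normalized values.
#' @param labels a `cluster_labels` (or named vector coercible via
#'   [as_cluster_labels()]).
#' @param min_pct,min_log2fc pre-filter defaults 0.1 and 0.25.
#' @return data.frame (`marker_table`): gene, cluster, log2fc, pct_in,
#'   pct_out, p, padj; sorted by cluster then p.
#' @export
find_all_markers <- function(expr, labels, min_pct = 0.1, min_log2fc = 0.25) {
  if (!inherits(labels, "cluster_labels")) labels <- as_cluster_labels(labels)
  lab <- labels$labels[colnames(expr$m)]
  if (anyNA(lab)) stop("labels do not cover all cells")
  gs <- group_stats(expr$m, lab)
  if (length(gs$clusters) < 2) stop("need at least two clusters")
  n_tot <- ncol(expr$m)
  tot_em <- rowSums(gs$expm1_sum); tot_det <- rowSums(gs$det)
  mT <- methods::as(Matrix::t(expr$m), "CsparseMatrix")

  res <- list()
  for (ci in seq_along(gs$clusters)) {
    cl <- gs$clusters[ci]; n_in <- gs$n[ci]; n_out <- n_tot - n_in
    if (n_in < 3) {
      warning("skipping cluster ", cl, " (fewer than 3 cells)")
      next
    }
    pct_in <- gs$det[, ci] / n_in
    pct_out <- (tot_det - gs$det[, ci]) / n_out
    l2fc <- log2((gs$expm1_sum[, ci] / n_in + 1) /
                   ((tot_em - gs$expm1_sum[, ci]) / n_out + 1))
    test <- which((pct_in >= min_pct | pct_out >= min_pct) &
                    abs(l2fc) >= min_log2fc)
    if (!length(test)) next
    in_mask <- lab == cl
    p <- vapply(test, function(g) {
      x <- numeric(n_tot)
      ptr <- (mT@p[g] + 1L):mT@p[g + 1L]
      if (mT@p[g + 1L] > mT@p[g]) x[mT@i[ptr] + 1L] <- mT@x[ptr]
      rank_sum_test(x[in_mask], x[!in_mask])$p
    }, numeric(1))
    res[[as.character(cl)]] <- data.frame(
      gene = rownames(expr$m)[test], cluster = as.character(cl),
      log2fc = l2fc[test], pct_in = pct_in[test], pct_out = pct_out[test],
      p = p, padj = stats::p.adjust(p, "BH"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(gene = character(), cluster = character(), log2fc = numeric(),
               pct_in = numeric(), pct_out = numeric(), p = numeric(),
               padj = numeric())
  }
  rownames(out) <- NULL
  out <- out[order(out$cluster, out$p, out$gene), ]
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Filter a marker table down to annotation markers
#'
#' Keeps rows with `padj <= max_padj`, `log2fc >= min_log2fc` and
#' `pct_in >= min_pct` (defaults 0.05, 4.0, 0.25) -- genes strongly and
#' specifically expressed in a single cluster, suitable for cell-type
#' annotation.
#'
#' @param table a `marker_table` from [find_all_markers()].
#' @param t a [pipeline_thresholds()].
#' @return the filtered `marker_table` (possibly empty).
#' @export
select_annotation_markers <- function(table, t = pipeline_thresholds()) {
  out <- table[table$padj <= t$anno_max_padj &
                 table$log2fc >= t$anno_min_log2fc &
                 table$pct_in >= t$anno_min_pct, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markers conserved across samples
#'
#' For each cluster, one-vs-rest tests are run separately within every
#' sample. A gene is retained only when its log2 fold change has the same
#' sign in every contributing sample; the combined p is the maximum across
#' samples (most conservative), the reported log2FC is the per-sample mean,
#' and rows are ranked by log2FC, descending. Samples contributing fewer
#' than `min_cells` cells to the cluster are excluded and recorded in the
#' `samples_used` column.
#'
#' @param expr an [expr_matrix()].
#' @param labels cluster labels.
#' @param clusters clusters to process (default all).
#' @param min_cells minimum in-cluster cells a sample must contribute.
#' @param min_pct,min_log2fc per-sample pre-filters as in
#'   [find_all_markers()].
#' @return data.frame: gene, cluster, log2fc (mean), p (max), padj (BH within
#'   cluster), pct_in, pct_out (means), n_samples, samples_used.
#' @export
find_conserved_markers <- function(expr, labels, clusters = NULL,
                                   min_cells = 3, min_pct = 0.1,
                                   min_log2fc = 0.25) {
  if (!inherits(labels, "cluster_labels")) labels <- as_cluster_labels(labels)
  lab <- labels$labels[colnames(expr$m)]
  samp <- expr$sample
  if (is.null(clusters)) clusters <- sort(unique(lab))
  out <- list()
  for (cl in clusters) {
    per_sample <- list()
    used <- character(0)
    for (s in unique(samp)) {
      cells <- which(samp == s)
      if (sum(lab[cells] == cl) < min_cells ||
          sum(lab[cells] != cl) < min_cells) next
      sub <- subset_cells(expr, cells)
      tab <- find_all_markers(sub,
                              as_cluster_labels(ifelse(lab[cells] == cl, cl, ".rest"),
                                                colnames(sub$m)),
                              min_pct = min_pct, min_log2fc = min_log2fc)
      per_sample[[s]] <- tab[tab$cluster == cl, ]
      used <- c(used, s)
    }
    if (length(per_sample) < 1) next
    genes <- Reduce(intersect, lapply(per_sample, `[[`, "gene"))
    if (!length(genes)) next
    l2fc <- vapply(per_sample, function(tt) tt$log2fc[match(genes, tt$gene)],
                   numeric(length(genes)))
    l2fc <- matrix(l2fc, nrow = length(genes))
    same_sign <- apply(l2fc, 1, function(v) all(v > 0) || all(v < 0))
    if (!any(same_sign)) next
    genes <- genes[same_sign]; l2fc <- l2fc[same_sign, , drop = FALSE]
    col_of <- function(field) {
      matrix(vapply(per_sample,
                    function(tt) tt[[field]][match(genes, tt$gene)],
                    numeric(length(genes))), nrow = length(genes))
    }
    pmax_ <- apply(col_of("p"), 1, max)
    pct_in <- rowMeans(col_of("pct_in"))
    pct_out <- rowMeans(col_of("pct_out"))
    df <- data.frame(gene = genes, cluster = cl, log2fc = rowMeans(l2fc),
                     p = pmax_, padj = stats::p.adjust(pmax_, "BH"),
                     pct_in = pct_in, pct_out = pct_out,
                     n_samples = length(used),
                     samples_used = paste(used, collapse = ","),
                     stringsAsFactors = FALSE)
    out[[cl]] <- df[order(-df$log2fc), ]
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(gene = character(), cluster = character(), log2fc = numeric(),
               p = numeric(), padj = numeric(), pct_in = numeric(),
               pct_out = numeric(), n_samples = integer(),
               samples_used = character())
  }
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Cluster-unique genes by the fold-ratio rule
#'
#' A gene is unique to cluster `c` when its mean log-normalized expression in
#' `c` is at least `fold` times the maximum mean over all other clusters,
#' and its maximum per-cluster mean is at least `floor` (genes with low
#' expression everywhere are not evaluated). Each gene can be assigned to at
#' most one cluster for any `fold > 1`.
#'
#' @param expr an [expr_matrix()].
#' @param labels cluster labels.
#' @param fold fold margin (default 3).
#' @param floor minimum max per-cluster mean, log-normalized units
#'   (default 0.25).
#' @return named list: per cluster, the character vector of unique gene ids
#'   (possibly empty).
#' @export
unique_fold_markers <- function(expr, labels, fold = 3, floor = 0.25) {
  if (!inherits(labels, "cluster_labels")) labels <- as_cluster_labels(labels)
  lab <- labels$labels[colnames(expr$m)]
  gs <- group_stats(expr$m, lab)
  if (length(gs$clusters) < 2) stop("need at least two clusters")
  means <- sweep(gs$logsum, 2, gs$n, "/")
  best <- max.col(means, ties.method = "first")
  best_val <- means[cbind(seq_len(nrow(means)), best)]
  second <- vapply(seq_len(nrow(means)), function(g) {
    max(means[g, -best[g]])
  }, numeric(1))
  tol <- 1e-9 * pmax(best_val, 1)   # guards exact-boundary cases like 3 x 0.1
  assigned <- best_val >= fold * second - tol & best_val >= floor & best_val > 0
  out <- lapply(seq_along(gs$clusters), function(ci) {
    rownames(expr$m)[assigned & best == ci]
  })
  names(out) <- gs$clusters
  out
}

#' Rare-cell detection by marker-count z-score
#'
#' Within each sample, cells with a zero raw count of the marker gene are
#' removed; the remaining counts are converted to z-scores
#' (`(x - mean) / sd`, sample sd with the n-1 denominator) and cells with
#' `z >= z_threshold` are selected. Samples with fewer than three non-zero
#' cells, or with zero spread, select no cells and are flagged. The call is
#' invariant to cell order and to adding zero-count cells.
#'
#' @param counts a [count_matrix()] of raw counts.
#' @param marker gene id of the marker (e.g. `"CALCA"`).
#' @param z_threshold selection threshold (default 1.96, the central-95%
#'   normal quantile).
#' @param per_sample compute per sample (default) or pooled.
#' @return list of class `rare_cell_call`: `calls` (data.frame barcode,
#'   sample, count, z) and `flagged` (character vector of degenerate
#'   samples).
#' @export
detect_rare_cells <- function(counts, marker, z_threshold = 1.96,
                              per_sample = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!marker %in% rownames(counts$m)) {
    stop("marker gene not found: ", marker)
  }
  x <- as.numeric(counts$m[marker, ])
  samp <- if (per_sample) counts$sample else rep("all", ncol(counts$m))
  calls <- list(); flagged <- character(0)
  for (s in unique(samp)) {
    idx <- which(samp == s & x > 0)
    if (length(idx) < 3 || stats::sd(x[idx]) == 0) {
      flagged <- c(flagged, s)
      next
    }
    z <- (x[idx] - mean(x[idx])) / stats::sd(x[idx])
    sel <- z >= z_threshold
    if (any(sel)) {
      calls[[s]] <- data.frame(
        barcode = colnames(counts$m)[idx[sel]], sample = s,
        count = x[idx[sel]], z = z[sel],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else {
    data.frame(barcode = character(), sample = character(),
               count = numeric(), z = numeric())
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, flagged = flagged), class = "rare_cell_call")
}

#' Module score of a gene set (binned controls)
#'
#' Per cell: mean log-normalized expression of the set genes minus the mean
#' over control genes. Genes are binned by their dataset-average expression
#' into `n_bins` equal-frequency bins, and each set gene contributes
#' `n_ctrl` control genes sampled (seeded, with replacement when the bin is
#' small) from its own bin, so the control matches the set's expression
#' profile.
#'
#' @param expr an [expr_matrix()].
#' @param gene_set character vector of gene ids.
#' @param n_bins,n_ctrl binning and control-pool sizes (defaults 24, 100).
#' @param seed integer seed.
#' @return named numeric vector: one score per cell.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  set <- intersect(gene_set, rownames(expr$m))
  if (!length(set)) stop("gene set has no genes in the matrix")
  avg <- Matrix::rowMeans(expr$m)
  n_bins <- min(n_bins, length(avg))
  bin <- ggplot_free_ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- rownames(expr$m)
  ctrl <- with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  s_score <- Matrix::colMeans(expr$m[set, , drop = FALSE])
  c_score <- Matrix::colMeans(expr$m[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(s_score - c_score), colnames(expr$m))
}

# equal-frequency binning of ranks into n bins
ggplot_free_ntile <- function(r, n) {
  as.integer(ceiling(r / (length(r) / n)))
}

#' Cell-cycle phase assignment
#'
#' Scores S-phase and G2/M gene panels with [module_score()] and assigns: S
#' when the S score exceeds the G2/M score and is positive; G2M when the
#' G2/M score exceeds the S score and is positive; G1 otherwise. An exact
#' positive tie is assigned to S.
#'
#' @param expr an [expr_matrix()].
#' @param s_genes,g2m_genes phase gene panels (see [gene_panel()]).
#' @param n_bins,n_ctrl forwarded to [module_score()].
#' @param seed seed forwarded to [module_score()].
#' @return data.frame: barcode, s_score, g2m_score, phase.
#' @export
assign_cell_cycle <- function(expr, s_genes, g2m_genes, n_bins = 24,
                              n_ctrl = 100, seed = 1L) {
  s <- module_score(expr, s_genes, n_bins, n_ctrl, seed = seed)
  g <- module_score(expr, g2m_genes, n_bins, n_ctrl, seed = seed + 1L)
  phase <- ifelse(s > g & s > 0, "S",
                  ifelse(g > s & g > 0, "G2M",
                         ifelse(s == g & s > 0, "S", "G1")))
  data.frame(barcode = colnames(expr$m), s_score = as.numeric(s),
             g2m_score = as.numeric(g), phase = phase,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bundled gene panels
#'
#' Plain-text gene panels shipped with the package: `"s_phase"` and
#' `"g2m_phase"` (canonical published human cell-cycle panels) and `"tds"`
#' (thyroid differentiation score genes: TG, TPO, TSHR, PAX8, ...).
#'
#' @param name panel name.
#' @return character vector of gene symbols.
#' @export
gene_panel <- function(name = c("s_phase", "g2m_phase", "tds")) {
  name <- match.arg(name)
  f <- system.file("extdata", "panels", paste0(name, ".txt"),
                   package = "snthyro")
  if (!nzchar(f)) stop("panel file missing: ", name)
  readLines(f)
}
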