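# shared fixtures and oracles, all built in code

# count_matrix from a dense matrix, with default gene/cell names
make_counts <- function(x, sample = "S1", gene_ids = NULL, barcodes = NULL) {
  x <- as.matrix(x)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(x)))
  if (is.null(barcodes)) barcodes <- sprintf("bc%03d", seq_len(ncol(x)))
  dimnames(x) <- list(gene_ids, barcodes)
  count_matrix(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
               sample = sample)
}

# expr_matrix straight from dense values (already "log-normalized")
make_expr <- function(x, sample = "S1", gene_ids = NULL, barcodes = NULL) {
  x <- as.matrix(x)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(x)))
  if (is.null(barcodes)) barcodes <- sprintf("bc%03d", seq_len(ncol(x)))
  dimnames(x) <- list(gene_ids, barcodes)
  expr_matrix(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
              sample = sample)
}

# adjusted Rand index (independent of any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sab <- sum(choose(tab, 2))
  e <- sa * sb / choose(n, 2)
  (sab - e) / ((sa + sb) / 2 - e)
}

# naive O(N) running-sum oracle for the weighted KS enrichment score:
# walks every position explicitly, independent of the package's hit-point
# shortcut
es_oracle <- function(scores, hit_mask, weight = 1) {
  N <- length(scores)
  w <- abs(scores)^weight
  nr <- sum(w[hit_mask])
  nh <- sum(hit_mask)
  dev <- cumsum(ifelse(hit_mask, if (nr > 0) w / nr else 1 / nh,
                       -1 / (N - nh)))
  maxP <- max(dev, 0)
  minP <- min(dev, 0)
  if (maxP > -minP + 1e-12) maxP else minP
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  u_obs <- sum(rank(v)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  r <- rank(v)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# small two-class simulation used across marker tests
two_class_sim <- function(seed = 42, n_cells = 600, fold = 8) {
  cp <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("A", "B"), "S1"))
  progs <- list(list(target = "A0", genes = 31:36, fold = fold,
                     baseline = 0.08),
                list(target = "B", genes = 41:46, fold = fold,
                     baseline = 0.08))
  cfg <- simulation_config(n_genes = 200, samples = c(S1 = n_cells),
                           class_proportions = cp,
                           subtype_proportions = c(A0 = 1),
                           marker_programs = progs, seed = seed)
  sim <- simulate_counts(cfg)
  sim$lab <- as_cluster_labels(stats::setNames(sim$truth$cells$class,
                                               sim$truth$cells$barcode))
  sim
}
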