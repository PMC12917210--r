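test_that("rank-sum test: exact small-sample branch matches enumeration", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)            # 2 x 1/C(6,3)
  expect_equal(r$statistic, 0)
  # identical multisets: U = n1 n2 / 2, p = 1
  r2 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
  expect_equal(r2$p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "empty")
  # every tie-free case with n1 + n2 <= 12 equals the enumeration oracle
  set.seed(19)
  for (n1 in 2:6) {
    for (n2 in n1:(12 - n1)) {
      v <- sample(100, n1 + n2)
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
      expect_equal(rank_sum_test(x, y)$p, wilcox_enum_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-sum normal approximation tracks the exact p", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)      # n = 14 forces the approximation
    expect_lt(abs(rank_sum_test(x, y)$p - wilcox_enum_p(x, y)), 0.02)
  }
})

test_that("rank-sum p-values are near-uniform under the null", {
  set.seed(31)
  p <- replicate(2000, rank_sum_test(rnorm(100), rnorm(100))$p)
  # U is rank-based, so p-values are discrete and tie; the KS distance is
  # still the right closeness measure
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("log2 fold change uses de-logged means with a pseudocount", {
  expect_equal(log2_fold_change(rep(log(4), 5), rep(0, 5)), 2)
  x <- c(0.3, 1.2, 0)
  expect_equal(log2_fold_change(x, x), 0)
  expect_equal(log2_fold_change(x, c(2, 0, 1)),
               -log2_fold_change(c(2, 0, 1), x))
})

test_that("find_all_markers surfaces planted programs and drops null genes", {
  sim <- two_class_sim(seed = 13, n_cells = 800)
  expr <- lognormalize(sim$counts)
  tab <- find_all_markers(expr, sim$lab)
  progA <- as.character(sim$truth$programs[["A0"]])
  rowsA <- tab[tab$cluster == "A" & tab$gene %in% progA & tab$log2fc > 0, ]
  expect_gte(nrow(rowsA), length(progA) - 1)
  expect_true(all(rowsA$padj < 0.05))
  expect_true(all(tab$padj >= tab$p))
  expect_true(all(tab$pct_in >= 0 & tab$pct_in <= 1))
  # BH is applied within cluster over the tests performed
  for (cl in unique(tab$cluster)) {
    sub <- tab[tab$cluster == cl, ]
    expect_equal(sub$padj, stats::p.adjust(sub$p, "BH"))
  }
  # a tiny cluster is skipped with a warning
  lab2 <- sim$lab$labels
  lab2[1:2] <- "tiny"
  lab2[-(1:2)] <- "rest"
  expect_warning(find_all_markers(expr, as_cluster_labels(lab2)), "skipping")
})

test_that("annotation-marker filter applies the boundary semantics", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"), cluster = "X",
    log2fc = c(4.0, 3.99, 5, 4.5),
    pct_in = c(0.25, 0.30, 0.24, 0.9),
    pct_out = 0.01,
    p = 0.001, padj = c(0.04, 0.04, 0.01, 0.06))
  out <- select_annotation_markers(tab, pipeline_thresholds())
  expect_identical(out$gene, "a")   # b fails fold, c fails pct, d fails padj
  expect_equal(nrow(select_annotation_markers(tab[0, ],
                                              pipeline_thresholds())), 0)
})

test_that("the rare-class marker passes the annotation filter on simulation", {
  cp <- matrix(c(0.98, 0.02), 2, 1,
               dimnames = list(c("Thyrocyte", "C.Cells"), "S1"))
  cfg <- simulation_config(n_genes = 150, samples = c(S1 = 800),
                           class_proportions = cp,
                           subtype_proportions = c(Thy0 = 1),
                           marker_programs = list(), seed = 3)
  sim <- simulate_counts(cfg)
  expr <- lognormalize(sim$counts)
  lab <- as_cluster_labels(stats::setNames(sim$truth$cells$class,
                                           sim$truth$cells$barcode))
  tab <- find_all_markers(expr, lab)
  ann <- select_annotation_markers(tab, pipeline_thresholds())
  expect_true("CALCA" %in% ann$gene[ann$cluster == "C.Cells"])
})

test_that("conserved markers require consistent sign and take the max p", {
  lab <- rep(c("one", "two"), c(12, 12))
  samp <- rep(c("s1", "s2"), each = 24)
  make_block <- function(gA_hi, gB_val_one, gB_val_two) {
    rbind(gA = ifelse(lab == "one", gA_hi, 0.1) + seq(0, 0.23, 0.01),
          gB = ifelse(lab == "one", gB_val_one, gB_val_two) +
            seq(0, 0.23, 0.01),
          gC = rep(c(0.5, 0.6), 12))
  }
  x <- cbind(make_block(2.0, 2.0, 0), make_block(2.4, 0, 2.0))
  colnames(x) <- paste0("c", 1:48)
  e <- expr_matrix(methods::as(Matrix::Matrix(x, sparse = TRUE),
                               "generalMatrix"),
                   sample = samp)
  labels <- as_cluster_labels(stats::setNames(rep(lab, 2)[1:48],
                                              colnames(x)))
  out <- find_conserved_markers(e, labels, clusters = "one")
  expect_true("gA" %in% out$gene)
  expect_false("gB" %in% out$gene)      # sign flips between samples
  # the combined p is the max over the per-sample tests
  p1 <- rank_sum_test(x["gA", 1:12], x["gA", 13:24])$p
  p2 <- rank_sum_test(x["gA", 25:36], x["gA", 37:48])$p
  expect_equal(out$p[out$gene == "gA"], max(p1, p2))
  # ranked by log2fc descending
  expect_false(is.unsorted(rev(out$log2fc)))
})

test_that("fold-ratio rule follows its margin, floor, and uniqueness", {
  # per-cluster means are exact when cells in a cluster share one value
  mk <- function(means, n = 4) {
    x <- matrix(rep(means, each = n), nrow = 1)
    e <- make_expr(x)
    lab <- as_cluster_labels(stats::setNames(
      rep(paste0("K", seq_along(means)), each = n), colnames(e$m)))
    list(e = e, lab = lab)
  }
  f <- mk(c(3.0, 0.9, 0.5))
  expect_identical(unique_fold_markers(f$e, f$lab, 3, 0.25)$K1, "g001")
  f2 <- mk(c(0.3, 0.1))
  expect_identical(unique_fold_markers(f2$e, f2$lab, 3, 0.25)$K1, "g001")
  f3 <- mk(c(0.2, 0.05))              # passes fold, fails floor
  expect_length(unique_fold_markers(f3$e, f3$lab, 3, 0.25)$K1, 0)
  f4 <- mk(c(2.0, 1.0, 1.0))          # fails fold
  expect_true(all(lengths(unique_fold_markers(f4$e, f4$lab, 3, 0.25)) == 0))
  # a gene is assigned to at most one cluster for any fold > 1
  set.seed(40)
  x <- matrix(runif(30 * 24), 30, 24)
  e <- make_expr(x)
  lab <- as_cluster_labels(stats::setNames(rep(c("a", "b", "c"), each = 8),
                                           colnames(e$m)))
  u <- unique_fold_markers(e, lab, 1.2, 0)
  expect_false(anyDuplicated(unlist(u)) > 0)
})

test_that("rare-cell z-scores follow the worked examples", {
  mk <- function(counts) {
    x <- matrix(0, 2, length(counts))
    x[1, ] <- counts
    x[2, ] <- 5
    make_counts(x, gene_ids = c("CALCA", "other"))
  }
  # [1, 2, 10]: z(10) ~ 1.149 < 1.96 -> nothing selected
  rc <- detect_rare_cells(mk(c(1, 2, 10)), "CALCA")
  expect_equal(nrow(rc$calls), 0)
  # ten 1s and one 50: z(50) ~ 3.015 -> the 50-count cell only
  rc2 <- detect_rare_cells(mk(c(rep(1, 10), 50)), "CALCA")
  expect_equal(rc2$calls$count, 50)
  expect_equal(rc2$calls$z, (50 - 60 / 11) / sd(c(rep(1, 10), 50)),
               tolerance = 1e-12)
  # all equal -> sd 0 -> flagged, nothing selected
  rc3 <- detect_rare_cells(mk(rep(4, 6)), "CALCA")
  expect_equal(nrow(rc3$calls), 0)
  expect_identical(rc3$flagged, "S1")
  expect_error(detect_rare_cells(mk(1:5), "NOPE"), "NOPE")
})

test_that("rare-cell calls ignore zero-count cells and cell order", {
  counts <- c(rep(1, 10), 50)
  x <- matrix(0, 2, length(counts) + 8)
  x[1, seq_along(counts)] <- counts
  x[2, ] <- 3
  cm <- make_counts(x, gene_ids = c("CALCA", "other"))
  base <- detect_rare_cells(cm, "CALCA")
  # dropping the zero-count cells changes nothing
  cm2 <- subset_cells(cm, seq_along(counts))
  expect_equal(detect_rare_cells(cm2, "CALCA")$calls$z, base$calls$z)
  # permuting cells changes nothing but the stored order
  perm <- sample(ncol(cm$m))
  cm3 <- subset_cells(cm, perm)
  out <- detect_rare_cells(cm3, "CALCA")
  expect_setequal(out$calls$barcode, base$calls$barcode)
  expect_equal(sort(out$calls$z), sort(base$calls$z))
})

test_that("module scores are zero on empty cells and near delta on shifts", {
  # 40 genes; the set sits delta above everything in its (single) bin
  delta <- 0.7
  x <- matrix(1, 40, 6)
  x[1:4, ] <- 1 + delta
  x[, 6] <- 0                        # an all-zero cell
  e <- make_expr(x)
  sc <- module_score(e, sprintf("g%03d", 1:4), n_bins = 1, n_ctrl = 50,
                     seed = 5)
  expect_equal(unname(sc[6]), 0)
  expect_equal(unname(sc[1]), delta, tolerance = delta * 0.2)
  expect_identical(sc, module_score(e, sprintf("g%03d", 1:4), n_bins = 1,
                                    n_ctrl = 50, seed = 5))
  expect_error(module_score(e, "absent"), "no genes")
})

test_that("cell-cycle phases recover a planted cycling structure", {
  s_genes <- sprintf("g%03d", 1:5)
  g2m_genes <- sprintf("g%03d", 6:10)
  n_per <- 30
  # plenty of background genes so expression bins hold genes beyond the
  # panels themselves
  x <- matrix(0.2, 120, 3 * n_per)
  x[1:5, 1:n_per] <- 2.0                          # S cells
  x[6:10, (n_per + 1):(2 * n_per)] <- 2.0         # G2M cells
  # quiescent cells express cycle genes below their expression-matched bin
  x[1:10, (2 * n_per + 1):(3 * n_per)] <- 0.1
  # constitutive genes whose dataset average matches the cycle panels, so
  # the panels' expression bins are not made of panel genes alone
  x[11:40, ] <- 0.75
  set.seed(6)
  x <- x + matrix(runif(length(x), 0, 0.05), nrow(x))
  e <- make_expr(x)
  cc <- assign_cell_cycle(e, s_genes, g2m_genes, n_bins = 6, seed = 2)
  truth <- rep(c("S", "G2M", "G1"), each = n_per)
  expect_gte(mean(cc$phase == truth), 0.9)
})
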