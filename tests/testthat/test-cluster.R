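test_that("run_pca matches an eigendecomposition oracle and is complete", {
  set.seed(11)
  x <- matrix(rnorm(200 * 30), 30, 200)   # 30 genes x 200 cells
  s <- structure(list(mat = x, hvg = rownames(x), sample = rep("S1", 200)),
                 class = "scaled_matrix")
  k <- 30
  p <- run_pca(s, k)
  expect_true(all(diff(p$variance) <= 1e-8))
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-6,
               ignore_attr = TRUE)
  # oracle: eigen of the cell covariance
  cx <- scale(t(x), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cx) / (nrow(cx) - 1), symmetric = TRUE)
  expect_equal(p$variance, ev$values[seq_len(k)], tolerance = 1e-8)
  # embeddings equal the centered input projected on the loadings
  expect_equal(p$embeddings, cx %*% p$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)
  # reconstruction from all components equals the centered input
  expect_equal(p$embeddings %*% t(p$loadings), cx, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("rank-deficient input yields near-zero trailing variances", {
  set.seed(2)
  base <- matrix(rnorm(2 * 100), 2, 100)
  x <- matrix(rnorm(10 * 2), 10, 2) %*% base   # rank 2, 10 genes x 100 cells
  s <- structure(list(mat = x, hvg = paste0("g", 1:10),
                      sample = rep("S1", 100)), class = "scaled_matrix")
  p <- run_pca(s, 10)
  expect_true(all(p$variance[3:10] < 1e-8))
  expect_error(run_pca(s, 200), "exceeds")
})

test_that("retain_components implements the cumulative-fraction rule", {
  expect_equal(retain_components(c(5, 3, 1, 0.5, 0.5), 0.9), 3)
  expect_equal(retain_components(rep(1, 50), 0.9), 45)
  expect_equal(retain_components(c(100, 1e-9, 1e-9), 0.9), 1)
  expect_error(retain_components(numeric(0)), "empty")
  # monotone in fraction
  v <- c(4, 2, 1, 1, 0.5, 0.2)
  ks <- vapply(seq(0.1, 1, 0.1), function(f) retain_components(v, f), 0)
  expect_true(all(diff(ks) >= 0))
})

test_that("SNN graph has Jaccard weights with self-inclusive neighborhoods", {
  # three identical points, k = 2: everyone's neighborhood is everyone
  emb <- matrix(0, 3, 2, dimnames = list(paste0("c", 1:3), NULL))
  g <- build_snn_graph(emb, k_neighbors = 2)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 1))
  expect_error(build_snn_graph(emb, k_neighbors = 3), "fewer cells")
  # two tight, far-separated blobs: no cross-blob edges survive pruning
  set.seed(3)
  blob <- rbind(matrix(rnorm(40 * 2, 0, 0.1), 40),
                matrix(rnorm(40 * 2, 50, 0.1), 40))
  rownames(blob) <- paste0("c", 1:80)
  g2 <- build_snn_graph(blob, k_neighbors = 10)
  ed <- igraph::as_edgelist(g2)
  side <- function(nm) as.integer(sub("c", "", nm)) > 40
  expect_true(all(side(ed[, 1]) == side(ed[, 2])))
})

test_that("SNN graph is invariant to cell order", {
  set.seed(8)
  emb <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(paste0("c", 1:60), NULL))
  g1 <- build_snn_graph(emb, 8)
  perm <- sample(60)
  g2 <- build_snn_graph(emb[perm, ], 8)
  key <- function(g) {
    e <- igraph::as_edgelist(g)
    o <- order(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    data.frame(a = pmin(e[, 1], e[, 2])[o], b = pmax(e[, 1], e[, 2])[o],
               w = round(igraph::E(g)$weight[o], 12))
  }
  expect_equal(key(g1), key(g2))
})

test_that("Leiden sweep recovers planted blobs and is deterministic", {
  # blobs dense relative to the neighborhood size, so each is near-complete
  # in the SNN graph and survives the whole sweep unsplit
  set.seed(5)
  emb <- rbind(matrix(rnorm(60 * 2, 0, 0.1), 60),
               matrix(rnorm(45 * 2, 20, 0.1), 45))
  rownames(emb) <- paste0("c", 1:105)
  truth <- rep(c(1, 2), c(60, 45))
  g <- build_snn_graph(emb, 30)
  labs <- cluster_multires(g, seq(0.1, 0.8, 0.1), seed = 42)
  for (r in names(labs)) {
    expect_equal(length(unique(labs[[r]])), 2)
    expect_equal(ari(labs[[r]][paste0("c", 1:105)], truth), 1)
  }
  # ids ordered by decreasing size: cluster 0 is the 60-cell blob
  expect_equal(sum(labs[["0.1"]] == 0), 60)
  labs2 <- cluster_multires(g, seq(0.1, 0.8, 0.1), seed = 42)
  expect_identical(labs, labs2)
})

test_that("resolution tree conserves flow and flags dispersed mini-clusters", {
  cells <- paste0("c", 1:400)
  l1 <- stats::setNames(rep(c(0L, 1L), each = 200), cells)
  # identical partition: identity edges with weight 1
  tr <- resolution_tree(structure(list(`0.1` = l1, `0.2` = l1),
                                  class = "multires_labels"))
  expect_true(all(tr$edges$weight == 1))
  expect_equal(nrow(tr$flags), 0)
  # one cluster splits evenly: each child fully from the same parent
  l2 <- l1; l2[1:100] <- 2L
  tr2 <- resolution_tree(structure(list(`0.1` = l1, `0.2` = l2),
                                   class = "multires_labels"))
  ch <- split(tr2$edges$weight, tr2$edges$child)
  expect_true(all(vapply(ch, sum, 0) == 1))
  # a 3-cell child drawing one cell from each of three parents -> flagged
  l3 <- stats::setNames(rep(c(0L, 1L, 2L), c(200, 150, 50)), cells)
  l4 <- l3; l4[c(1, 201, 351)] <- 3L
  tr3 <- resolution_tree(structure(list(`0.1` = l3, `0.2` = l4),
                                   class = "multires_labels"))
  expect_true(any(tr3$flags$resolution == "0.2"))
  expect_error(resolution_tree(structure(list(`0.1` = l1),
                                         class = "multires_labels")),
               "two resolutions")
})

test_that("schema selection takes plans, defaults past flagged resolutions", {
  cells <- paste0("c", 1:400)
  l1 <- stats::setNames(rep(c(0L, 1L), each = 200), cells)
  l2 <- stats::setNames(rep(c(0L, 1L, 2L, 3L), each = 100), cells)
  l3 <- l2; l3[c(1, 101, 201)] <- 4L   # dispersed 3-cell cluster
  labs <- structure(list(`0.1` = l1, `0.2` = l2, `0.3` = l3),
                    class = "multires_labels")
  tree <- resolution_tree(labs)
  # explicit plan: pass-through
  out <- select_schema(labs, tree, plan = list(resolution = "0.2"))
  expect_equal(unname(out$labels), as.character(unname(l2)))
  # default: highest resolution without an over-clustering flag is 0.2
  def <- select_schema(labs, tree)
  expect_match(def$provenance, "0.2")
  expect_error(select_schema(labs, tree, plan = list(resolution = "0.9")),
               "unknown resolution")
  # merging through the plan combines counts
  pl <- select_schema(labs, tree,
                      plan = list(resolution = "0.2",
                                  merge = list(AB = c("2", "3"))))
  expect_equal(sum(pl$labels == "AB"), 200)
})

test_that("merge_clusters unions groups and validates them", {
  lab <- as_cluster_labels(stats::setNames(rep(c("Fib_a", "Fib_b", "T"),
                                               c(30, 20, 10)),
                                           paste0("c", 1:60)))
  m <- merge_clusters(lab, list(Fibroblasts = c("Fib_a", "Fib_b")))
  expect_equal(sum(m$labels == "Fibroblasts"), 50)
  expect_identical(merge_clusters(lab, list())$labels, lab$labels)
  expect_error(merge_clusters(lab, list(a = c("Fib_a"), b = c("Fib_a", "T"))),
               "overlapping")
  expect_error(merge_clusters(lab, list(a = "nope")), "unknown cluster")
  allm <- merge_clusters(lab, list(all = c("Fib_a", "Fib_b", "T")))
  expect_equal(unique(unname(allm$labels)), "all")
})

test_that("every labeling partitions the cell set", {
  sim <- two_class_sim(seed = 77, n_cells = 400)
  t <- pipeline_thresholds(min_genes = 20)
  filt <- filter_cells(sim$counts, compute_cell_qc(sim$counts), t)
  expr <- lognormalize(filt)
  scl <- scale_center(expr, select_hvgs(filt, 100))
  pca <- run_pca(scl, 20)
  g <- build_snn_graph(pca, 15, n_dims = retain_components(pca, 0.9))
  labs <- cluster_multires(g, c(0.2, 0.5), seed = 1)
  for (r in names(labs)) {
    expect_setequal(names(labs[[r]]), colnames(filt$m))
    expect_false(anyNA(labs[[r]]))
  }
  final <- select_schema(labs, resolution_tree(labs))
  expect_setequal(names(final$labels), colnames(filt$m))
})
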