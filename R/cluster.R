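#' Principal component analysis of a scaled matrix
#'
#' Exact PCA (singular value decomposition of the centered cells x genes
#' matrix). Component signs are fixed so the loading of largest magnitude in
#' each component is positive, making results reproducible across runs and
#' platforms. The decomposition itself is deterministic; `seed` is accepted
#' for interface uniformity with the stochastic stages.
#'
#' @param scaled a `scaled_matrix` from [scale_center()].
#' @param k number of components to compute (default 50).
#' @param seed unused by the exact solver; kept for pipeline plumbing.
#' @return list of class `pca_result`: `loadings` (genes x k, orthonormal),
#'   `embeddings` (cells x k), `variance` (length k, non-increasing).
#' @export
run_pca <- function(scaled, k = 50, seed = 1L) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  x <- t(scaled$mat)                      # cells x genes
  k <- as.integer(k)
  if (k > min(dim(x))) stop("k exceeds min(genes, cells)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    w <- load[which.max(abs(load[, j])), j]
    if (w < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  emb <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  structure(list(loadings = load, embeddings = emb,
                 variance = pc$sdev[seq_len(k)]^2,
                 center = pc$center, sample = scaled$sample),
            class = "pca_result")
}

#' Number of components reaching a cumulative variance fraction
#'
#' The smallest `k` whose cumulative variance, as a fraction of the total
#' variance over the *computed* components, reaches `fraction`. Monotone in
#' `fraction`.
#'
#' @param pca a `pca_result` (or a numeric variance vector).
#' @param fraction target fraction in (0, 1].
#' @return integer count of components to retain.
#' @export
retain_components <- function(pca, fraction = 0.90) {
  v <- if (inherits(pca, "pca_result")) pca$variance else as.numeric(pca)
  if (!length(v)) stop("empty variance vector")
  stopifnot(fraction > 0, fraction <= 1)
  which(cumsum(v) / sum(v) >= fraction - 1e-12)[1]
}

# blocked brute-force k-nearest-neighbours (Euclidean), self included
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k + 1L)
  block <- max(1L, min(n, as.integer(2e7 / n)))
  for (b0 in seq(0L, n - 1L, by = block)) {
    rows <- (b0 + 1L):min(b0 + block, n)
    d2 <- -2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    d2 <- d2 + sq[rows]                 # row term (recycles down columns)
    d2 <- sweep(d2, 2, sq, "+")         # column term
    for (r in seq_along(rows)) {
      o <- order(d2[r, ])[seq_len(k + 1L)]
      i <- rows[r]
      if (!i %in% o) o <- c(i, o[seq_len(k)])  # tie guard: keep self
      idx[i, ] <- o
    }
  }
  idx
}

#' Build a shared-nearest-neighbor graph
#'
#' k-nearest-neighbors by Euclidean distance in the embedding (each cell's
#' neighbor set contains itself plus its `k_neighbors` nearest others); edge
#' weights are the Jaccard overlap of neighbor sets; weights at or below
#' `prune` are removed.
#'
#' @param embedding numeric matrix (cells x dims) with cell rownames, or a
#'   `pca_result` (its embeddings are used).
#' @param k_neighbors neighborhood size (default 20).
#' @param prune pruning floor for Jaccard weights (default 1/15).
#' @param n_dims optionally restrict to the first `n_dims` embedding columns.
#' @return an [igraph::graph] (undirected, weighted), vertices named by cell.
#' @export
build_snn_graph <- function(embedding, k_neighbors = 20, prune = 1 / 15,
                            n_dims = NULL) {
  if (inherits(embedding, "pca_result")) embedding <- embedding$embeddings
  if (!is.null(n_dims)) embedding <- embedding[, seq_len(n_dims), drop = FALSE]
  n <- nrow(embedding)
  if (n < k_neighbors + 1L) stop("fewer cells than k_neighbors + 1")
  if (is.null(rownames(embedding))) rownames(embedding) <- as.character(seq_len(n))
  nn <- knn_indices(embedding, k_neighbors)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)          # |A_i  intersect  A_j|
  inter <- methods::as(inter, "TsparseMatrix")
  keep <- inter@i < inter@j
  i <- inter@i[keep] + 1L; j <- inter@j[keep] + 1L
  s <- inter@x[keep]
  w <- s / (2 * (k_neighbors + 1L) - s)     # Jaccard
  ok <- w > prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(embedding)[i[ok]],
               to = rownames(embedding)[j[ok]], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = rownames(embedding)))
  g
}

# relabel a membership vector: ids 0-based, ordered by decreasing cluster
# size, ties broken by first-occurring cell
relabel_by_size <- function(member) {
  sz <- table(member)
  first <- vapply(names(sz), function(cl) which(member == cl)[1], 0)
  ord <- names(sz)[order(-as.integer(sz), first)]
  stats::setNames(match(member, ord) - 1L, names(member))
}

#' Leiden clustering across a resolution sweep
#'
#' Runs Leiden modularity optimization on the SNN graph once per resolution
#' with a fixed seed. Cluster ids are 0-based and ordered by decreasing size
#' (ties broken by first-occurring cell), so labelings are stable across
#' runs.
#'
#' @param graph weighted graph from [build_snn_graph()].
#' @param resolutions numeric vector of resolution parameters.
#' @param seed integer seed (reset before every resolution).
#' @param n_iterations Leiden iterations per run.
#' @return named list of class `multires_labels`: per resolution, an integer
#'   vector of 0-based cluster ids named by cell.
#' @export
cluster_multires <- function(graph, resolutions = seq(0.1, 0.8, by = 0.1),
                             seed = 1L, n_iterations = 10L) {
  if (!length(resolutions)) stop("resolutions must be non-empty")
  if (igraph::ecount(graph) == 0) stop("graph has no edges")
  out <- lapply(resolutions, function(res) {
    memb <- with_seed(seed, {
      cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                   resolution = res,
                                   weights = igraph::E(graph)$weight,
                                   n_iterations = n_iterations)
      stats::setNames(igraph::membership(cl), igraph::V(graph)$name)
    })
    relabel_by_size(memb)
  })
  names(out) <- sprintf("%g", resolutions)
  structure(out, resolutions = resolutions, class = "multires_labels")
}

#' Flow tree between consecutive resolutions
#'
#' For every pair of consecutive resolutions, edges connect parent clusters
#' to child clusters, weighted by the fraction of the child's cells that come
#' from the parent (incoming weights sum to 1 per child). A child is flagged
#' as potential over-clustering when it receives less than half of its cells
#' from any single parent *and* holds fewer than 1% of all cells.
#'
#' @param labels a `multires_labels` from [cluster_multires()].
#' @return list of class `resolution_tree`: `nodes` (resolution, cluster,
#'   size), `edges` (parent_res, parent, child_res, child, weight), `flags`
#'   (resolution, cluster rows that tripped the heuristic).
#' @export
resolution_tree <- function(labels) {
  res <- names(labels)
  if (length(res) < 2) stop("need at least two resolutions")
  cells <- names(labels[[1]])
  for (r in res) {
    if (!identical(sort(names(labels[[r]])), sort(cells))) {
      stop("resolutions cover different cell sets")
    }
  }
  n <- length(cells)
  nodes <- do.call(rbind, lapply(res, function(r) {
    sz <- table(labels[[r]])
    data.frame(resolution = r, cluster = as.integer(names(sz)),
               size = as.integer(sz), stringsAsFactors = FALSE)
  }))
  edges <- NULL; flags <- NULL
  for (k in seq_len(length(res) - 1)) {
    pa <- labels[[res[k]]][cells]; ch <- labels[[res[k + 1]]][cells]
    tab <- table(pa, ch)
    frac <- sweep(tab, 2, colSums(tab), "/")
    tt <- as.data.frame(tab, stringsAsFactors = FALSE)
    tt <- tt[tt$Freq > 0, ]
    edges <- rbind(edges, data.frame(
      parent_res = res[k], parent = as.integer(tt$pa),
      child_res = res[k + 1], child = as.integer(tt$ch),
      weight = tt$Freq / as.integer(table(ch)[tt$ch]),
      stringsAsFactors = FALSE))
    child_sz <- table(ch)
    weak <- colnames(frac)[apply(frac, 2, max) < 0.5 &
                             as.integer(child_sz[colnames(frac)]) < 0.01 * n]
    if (length(weak)) {
      flags <- rbind(flags, data.frame(resolution = res[k + 1],
                                       cluster = as.integer(weak),
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 flags = if (is.null(flags)) {
                   data.frame(resolution = character(), cluster = integer())
                 } else flags),
            class = "resolution_tree")
}

#' Assemble the final clustering schema
#'
#' `plan` may name a resolution to take as-is (`list(resolution = "0.3")`),
#' optionally with merges (`list(resolution = "0.4", merge =
#' list(Fibroblasts = c(2, 5)))`). With `plan = NULL` the default rule picks
#' the highest resolution whose tree shows no over-clustering flag.
#'
#' @param labels a `multires_labels`.
#' @param tree the matching `resolution_tree`.
#' @param plan list, or NULL for the default rule.
#' @return list of class `cluster_labels`: `labels` (named character vector,
#'   one final cluster name per cell) and `provenance`.
#' @export
select_schema <- function(labels, tree = resolution_tree(labels), plan = NULL) {
  res_names <- names(labels)
  if (is.null(plan)) {
    flagged <- unique(tree$flags$resolution)
    ok <- res_names[!res_names %in% flagged]
    if (!length(ok)) ok <- res_names[1]
    r <- ok[length(ok)]
    plan <- list(resolution = r)
    prov <- sprintf("default rule: highest unflagged resolution (%s)", r)
  } else {
    r <- as.character(plan$resolution)
    if (!r %in% res_names) stop("plan references unknown resolution: ", r)
    prov <- sprintf("plan: resolution %s", r)
  }
  lab <- labels[[r]]
  out <- structure(list(labels = stats::setNames(as.character(lab), names(lab)),
                        provenance = prov),
                   class = "cluster_labels")
  if (!is.null(plan$merge)) {
    groups <- lapply(plan$merge, as.character)
    out <- merge_clusters(out, groups)
  }
  out
}

#' Merge named clusters
#'
#' Cells of each group are relabeled to one new name (the group's name in
#' `groups`, else the member names joined by `+`); other cells are unchanged.
#'
#' @param labels a `cluster_labels`.
#' @param groups list of character vectors of existing cluster names;
#'   groups must be disjoint.
#' @return updated `cluster_labels`.
#' @export
merge_clusters <- function(labels, groups) {
  stopifnot(inherits(labels, "cluster_labels"))
  if (!length(groups)) return(labels)
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) stop("overlapping merge groups")
  unknown <- setdiff(all_members, unique(labels$labels))
  if (length(unknown)) stop("unknown cluster(s): ",
                            paste(unknown, collapse = ", "))
  lab <- labels$labels
  for (k in seq_along(groups)) {
    new <- names(groups)[k]
    if (is.null(new) || !nzchar(new)) new <- paste(groups[[k]], collapse = "+")
    lab[lab %in% groups[[k]]] <- new
  }
  labels$labels <- lab
  labels$provenance <- paste0(labels$provenance, "; merged: ",
                              paste(vapply(groups, paste, "", collapse = ","),
                                    collapse = " | "))
  labels
}

#' Make a cluster_labels object from a plain vector
#' @param x character/factor vector of labels named by cell (or `cells`
#'   supplies names).
#' @param cells optional cell names.
#' @return `cluster_labels`.
#' @export
as_cluster_labels <- function(x, cells = names(x)) {
  lab <- stats::setNames(as.character(x), cells)
  if (is.null(names(lab))) stop("labels need cell names")
  structure(list(labels = lab, provenance = "external"),
            class = "cluster_labels")
}
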