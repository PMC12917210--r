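#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then members (tab-separated).
#' Members are deduplicated; duplicate set names and lines with fewer than
#' three fields are errors.
#'
#' @param path path to a GMT file.
#' @param source_tag optional tag (e.g. "hallmark") stored as an attribute.
#' @return named list of character vectors, class `gene_set_collection`.
#' @export
read_gmt <- function(path, source_tag = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) stop("malformed GMT line ", short[1],
                          " (fewer than 3 fields)")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  structure(sets, source = source_tag, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Rank genes by cross-cluster z-score of mean expression
#'
#' For each gene, the per-cluster means of log-normalized expression are
#' computed; the score of the target cluster is the z of its mean relative
#' to the mean and sd (n-1) of the per-cluster means across all clusters.
#' Genes whose per-cluster means have zero variance are excluded. Sorted
#' descending, ties broken by gene id.
#'
#' @param expr an [expr_matrix()].
#' @param labels cluster labels.
#' @param cluster target cluster name.
#' @return data.frame (`ranked_list`): gene, score; descending.
#' @export
rank_by_z <- function(expr, labels, cluster) {
  if (!inherits(labels, "cluster_labels")) labels <- as_cluster_labels(labels)
  lab <- labels$labels[colnames(expr$m)]
  gs <- group_stats(expr$m, lab)
  if (length(gs$clusters) < 2) stop("z undefined with a single cluster")
  ci <- match(as.character(cluster), gs$clusters)
  if (is.na(ci)) stop("unknown cluster: ", cluster)
  means <- sweep(gs$logsum, 2, gs$n, "/")
  mu <- rowMeans(means)
  sd_ <- apply(means, 1, stats::sd)
  ok <- sd_ > 0
  z <- (means[ok, ci] - mu[ok]) / sd_[ok]
  df <- data.frame(gene = rownames(expr$m)[ok], score = as.numeric(z),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  df
}

#' Rank a marker table by log2 fold change
#'
#' @param table a `marker_table` restricted to one cluster (or pass
#'   `cluster` to restrict).
#' @param cluster optional cluster to restrict to.
#' @return a `ranked_list` (gene, score), descending by log2FC, ties by gene
#'   id; duplicate gene rows are an error.
#' @export
rank_by_log2fc <- function(table, cluster = NULL) {
  if (!is.null(cluster)) table <- table[table$cluster == cluster, ]
  if (!nrow(table)) stop("empty marker table")
  if (anyDuplicated(table$gene)) {
    stop("duplicate gene rows: ", table$gene[duplicated(table$gene)][1])
  }
  df <- data.frame(gene = table$gene, score = table$log2fc,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  df
}

# ES from sorted hit positions; weights w = |score|^p at those positions.
# Returns c(ES, extremum position). The running sum rises by w/NR at hits
# and falls by 1/(N - Nh) at misses; its extrema occur just before or at
# hit positions, which is all this evaluates. An exact tie between the
# positive and negative extremum resolves to the negative one (the usual
# preranked convention).
es_walk <- function(pos, w, N) {
  Nh <- length(pos)
  NR <- sum(w)
  if (NR <= 0) w[] <- 1 / Nh else w <- w / NR
  miss <- 1 / (N - Nh)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(Nh)) * miss
  before <- c(0, cw[-Nh]) - (pos - seq_len(Nh)) * miss
  iM <- which.max(after)
  im <- which.min(before)
  maxP <- max(after[iM], 0)
  minP <- min(before[im], 0)
  if (maxP > -minP + 1e-12) c(maxP, pos[iM]) else c(minP, pos[im])
}

#' Weighted KS enrichment score of a set in a ranked list
#'
#' The classic preranked statistic: walking down the ranked list, the
#' running sum gains `|score|^weight / sum_set |score|^weight` at set genes
#' and loses `1 / (N - n_set)` at others; the enrichment score is the
#' signed maximum deviation from zero (an exact tie between the positive and
#' negative extremum resolves to the negative one). The leading edge is the set genes at
#' or before the extremum (for positive ES) or at or after it (negative
#' ES). If all hit scores are zero the hit weights fall back to uniform.
#'
#' @param ranked a `ranked_list` (gene, score; descending).
#' @param set character vector of gene ids.
#' @param weight exponent on `|score|` (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return list: `ES` (in `[-1, 1]`), `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- which(genes %in% set)
  if (!length(hit)) stop("empty intersection between set and ranked list")
  if (length(hit) == N) stop("set covers the whole ranked universe")
  w <- abs(ranked$score[hit])^weight
  es <- es_walk(hit, w, N)
  le <- if (es[1] > 0) genes[hit[hit <= es[2]]]
        else if (es[1] < 0) genes[hit[hit >= es[2]]]
        else character(0)
  list(ES = es[1], leading_edge = le)
}

#' Permutation p-values and normalized scores for a collection
#'
#' Gene-label permutation null: for each set size, random same-size gene
#' sets are drawn from the ranked universe and scored; the p-value is the
#' add-one estimator `(1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`. NES
#' divides the observed ES by the mean `|ES_perm|` of the same sign.
#' p-values are Benjamini-Hochberg adjusted across all sets in the
#' collection; records at `padj <= padj_cutoff` are flagged `retained`.
#' Sets with no gene in the ranked universe are dropped with a warning.
#'
#' @param ranked a `ranked_list`.
#' @param sets a `gene_set_collection` (named list).
#' @param n_perm number of permutations (>= 100).
#' @param weight exponent forwarded to [enrichment_score()].
#' @param seed integer seed; permutations are deterministic given it.
#' @param padj_cutoff retention threshold (default 0.1).
#' @return data.frame (`enrichment_records`): set, size, ES, NES, p, padj,
#'   retained, leading_edge (comma-joined).
#' @export
permutation_pvalues <- function(ranked, sets, n_perm = 1000, weight = 1,
                                seed = 1L, padj_cutoff = 0.1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- ranked$gene
  N <- length(genes)
  absw <- abs(ranked$score)^weight
  inter <- lapply(sets, intersect, genes)
  empty <- lengths(inter) == 0 | lengths(inter) >= N
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) with empty/universe overlap")
    inter <- inter[!empty]
  }
  if (!length(inter)) stop("no usable sets")
  sizes <- lengths(inter)
  perm_es <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      es_k <- vapply(seq_len(n_perm), function(i) {
        pos <- sort.int(sample.int(N, k))
        es_walk(pos, absw[pos], N)[1]
      }, numeric(1))
      out[[as.character(k)]] <- es_k
    }
    out
  })
  rows <- lapply(names(inter), function(nm) {
    obs <- enrichment_score(ranked, inter[[nm]], weight = weight)
    ep <- perm_es[[as.character(length(inter[[nm]]))]]
    p <- (1 + sum(abs(ep) >= abs(obs$ES) - 1e-12)) / (n_perm + 1)
    same <- ep[sign(ep) == sign(obs$ES)]
    nes <- if (length(same)) obs$ES / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = length(inter[[nm]]), ES = obs$ES, NES = nes,
               p = p, leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$p, "BH")
  res$retained <- res$padj <= padj_cutoff
  res <- res[, c("set", "size", "ES", "NES", "p", "padj", "retained",
                 "leading_edge")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_records", "data.frame")
  res
}

#' Shared and unique retained pathways across clusters
#'
#' `shared` is the intersection of the retained set names across every
#' cluster; `unique[[c]]` is the retained sets of cluster `c` minus the
#' union of every other cluster's retained sets.
#'
#' @param results named list: per cluster, an `enrichment_records` table (or
#'   a character vector of retained set names).
#' @param cutoff adjusted-p cutoff applied when tables are given.
#' @return list: `shared` (character), `unique` (named list of character).
#' @export
shared_unique_pathways <- function(results, cutoff = 0.1) {
  if (length(results) < 2) stop("need results for at least two clusters")
  retained <- lapply(results, function(r) {
    if (is.character(r)) r else r$set[r$padj <= cutoff]
  })
  shared <- Reduce(intersect, retained)
  uniq <- lapply(seq_along(retained), function(i) {
    setdiff(retained[[i]], unlist(retained[-i]))
  })
  names(uniq) <- names(retained)
  list(shared = shared, unique = uniq)
}
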