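#' Simulation configuration for synthetic snRNA-seq counts
#'
#' Builds and validates the configuration of the negative-binomial count
#' simulator. The defaults emulate the population structure of a three-donor
#' pediatric thyroid dataset: a dominant thyrocyte class (~92% of cells) split
#' into seven latent subtypes (one ~61% baseline subtype carrying no unique
#' program), five minor stromal/immune classes between ~0.4% and ~4%, and a
#' rare calcitonin-producing (C cell) class around 0.04% defined by a single
#' high-count marker gene (`CALCA`). Per-sample composition shifts (e.g. an
#' immune-enriched second donor) are part of the defaults.
#'
#' The count model is gene-wise negative binomial: each gene has a lognormal
#' baseline relative abundance, multiplied by the fold factors of any marker
#' program planted for the cell's class or subtype, renormalized to a relative
#' expression profile and scaled by a per-cell sequencing depth. Mitochondrial
#' genes receive a per-cell Beta-distributed share of the depth; the default
#' Beta(1.3, 55) keeps the share below 15% in well over 99% of cells.
#'
#' @param n_genes number of genes (>= 50); includes 13 mitochondrial genes and
#'   the rare-class marker.
#' @param samples named integer vector: cells per sample.
#' @param class_proportions matrix (classes x samples) of per-sample class
#'   proportions; each column must sum to 1.
#' @param subtype_proportions named numeric simplex over subtypes of the
#'   dominant class (first class of `class_proportions`).
#' @param marker_programs list of `list(target=, genes=, fold=)` entries;
#'   `target` is a class or subtype name, `genes` integer gene indices,
#'   `fold` a positive multiplier applied to those genes' baseline means.
#'   `NULL` builds the default programs (see Details).
#' @param rare_class `list(class=, gene=, mean_count=, zero_inflation=,
#'   background_mean=)`: the rare class name, its marker gene index, the mean
#'   marker count in rare cells, the probability that a non-rare cell has a
#'   zero marker count, and the mean of the (shifted-Poisson) non-zero
#'   background counts.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of baseline
#'   relative gene abundances.
#' @param marker_baseline relative abundance assigned to program marker genes
#'   outside their target population (markers are near-off elsewhere).
#' @param dispersion negative-binomial size parameter (shared across genes).
#' @param depth_meanlog,depth_sdlog lognormal parameters of per-cell depth
#'   (total molecules); defaults target a median around 2,300 molecules so
#'   detected genes fall mostly within `target_genes_per_cell`.
#' @param mito_beta length-2 numeric, Beta shape parameters of the per-cell
#'   mitochondrial share of depth.
#' @param target_genes_per_cell length-2 range of intended detected genes.
#' @param doublet_rate,ambient_fraction artifact rates in `[0,1)` consumed by
#'   [inject_artifacts()]; the base simulator itself emits clean cells.
#' @param n_program_genes_subtype,n_program_genes_class program sizes used
#'   when building default programs.
#' @param subtype_fold,class_fold default program fold changes.
#' @param seed integer; fully determines the simulator output.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 2000,
    samples = c(C1 = 13746, C2 = 12362, C3 = 10869),
    class_proportions = NULL,
    subtype_proportions = c(Thy0 = 0.6111, Thy1 = 0.1450, Thy2 = 0.1041,
                            Thy3 = 0.0611, Thy4 = 0.0420, Thy5 = 0.0260,
                            Thy6 = 0.0107),
    marker_programs = NULL,
    rare_class = list(class = "C.Cells", gene = NA_integer_, mean_count = 25,
                      zero_inflation = 0.95, background_mean = 1.3),
    baseline_meanlog = 0, baseline_sdlog = 1.1,
    marker_baseline = 0.12,
    dispersion = 2,
    depth_meanlog = log(2300), depth_sdlog = 0.35,
    mito_beta = c(1.3, 55),
    target_genes_per_cell = c(200, 3000),
    doublet_rate = 0, ambient_fraction = 0,
    n_program_genes_subtype = 25, n_program_genes_class = 10,
    subtype_fold = 6, class_fold = 8,
    seed = 1L) {

  if (n_genes < 50) stop("configuration error: n_genes must be >= 50")
  if (length(samples) < 1 || any(samples < 1)) {
    stop("configuration error: every sample needs at least one cell")
  }
  if (is.null(names(samples))) names(samples) <- paste0("S", seq_along(samples))

  if (is.null(class_proportions)) {
    # per-sample composition of a three-donor thyroid: dominant thyrocytes,
    # minor stromal/immune classes, rare C cells (absent from donor 3),
    # immune-enriched donor 2
    tab <- cbind(
      C1 = c(12736, 366, 209, 269,  98, 54, 13,   1),
      C2 = c(10909, 525,  57, 154, 477, 75,  2, 163),
      C3 = c(10357, 196,  79, 134,  62, 41,  0,   0))
    rownames(tab) <- c("Thyrocyte", "Endothelial_L", "Endothelial_V",
                       "Fibroblasts", "Mixed_Tcells", "Myeloid",
                       "C.Cells", "Mixed_Bcells")
    props <- sweep(tab, 2, colSums(tab), "/")
    if (length(samples) <= ncol(props) && all(names(samples) %in% colnames(props))) {
      class_proportions <- props[, names(samples), drop = FALSE]
    } else {
      class_proportions <- props[, rep_len(seq_len(ncol(props)), length(samples)),
                                 drop = FALSE]
      colnames(class_proportions) <- names(samples)
    }
  }
  class_proportions <- as.matrix(class_proportions)
  if (ncol(class_proportions) != length(samples)) {
    stop("configuration error: class_proportions needs one column per sample")
  }
  colnames(class_proportions) <- names(samples)
  if (any(class_proportions < 0) ||
      any(abs(colSums(class_proportions) - 1) > 1e-9)) {
    stop("configuration error: class proportions must be a simplex per sample")
  }
  subtype_proportions <- subtype_proportions / 1  # keep names
  if (any(subtype_proportions < 0)) {
    stop("configuration error: subtype proportions must be non-negative")
  }
  subtype_proportions <- subtype_proportions / sum(subtype_proportions)

  mito_idx <- seq_len(13)
  mito_names <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
                  "MT-ND6", "MT-CYB", "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6",
                  "MT-ATP8")
  if (is.na(rare_class$gene)) rare_class$gene <- 14L
  if (rare_class$gene %in% mito_idx) {
    stop("configuration error: rare marker cannot be mitochondrial")
  }

  cfg <- list(
    n_genes = as.integer(n_genes), samples = samples,
    class_proportions = class_proportions,
    subtype_proportions = subtype_proportions,
    marker_programs = marker_programs,
    rare_class = rare_class,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    marker_baseline = marker_baseline,
    dispersion = dispersion,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    mito_beta = mito_beta,
    target_genes_per_cell = target_genes_per_cell,
    doublet_rate = doublet_rate, ambient_fraction = ambient_fraction,
    mito_gene_indices = mito_idx, mito_gene_names = mito_names,
    seed = as.integer(seed))

  if (is.null(marker_programs)) {
    cfg$marker_programs <- default_marker_programs(
      cfg, n_program_genes_subtype, n_program_genes_class,
      subtype_fold, class_fold)
  }
  for (pr in cfg$marker_programs) {
    if (pr$fold <= 0) stop("configuration error: fold multipliers must be > 0")
    if (any(pr$genes %in% mito_idx) || any(pr$genes == rare_class$gene)) {
      stop("configuration error: program genes overlap mito/rare marker genes")
    }
  }
  structure(cfg, class = "simulation_config")
}

# disjoint default programs: one block of marker genes per dominant-class
# subtype (except the baseline subtype Thy0) and per minor class
default_marker_programs <- function(cfg, n_sub, n_cls, fold_sub, fold_cls) {
  reserved <- c(cfg$mito_gene_indices, cfg$rare_class$gene)
  pool <- setdiff(seq_len(cfg$n_genes), reserved)
  subtypes <- names(cfg$subtype_proportions)
  classes <- setdiff(rownames(cfg$class_proportions),
                     c(rownames(cfg$class_proportions)[1], cfg$rare_class$class))
  targets <- c(subtypes[-1], classes)
  sizes <- c(rep(n_sub, length(subtypes) - 1), rep(n_cls, length(classes)))
  folds <- c(rep(fold_sub, length(subtypes) - 1), rep(fold_cls, length(classes)))
  if (sum(sizes) > length(pool) / 2) {
    # small gene panels: shrink programs proportionally (>= 2 genes each)
    sizes <- pmax(2L, floor(sizes * (length(pool) / 2) / sum(sizes)))
  }
  if (sum(sizes) > length(pool)) {
    stop("configuration error: not enough genes for default marker programs")
  }
  # subtype programs emulate mitochondrial-ETC / ribosomal / cytoskeletal
  # modules: moderate-abundance genes elevated several-fold. Minor-class
  # programs emulate cell-type annotation markers: near-off outside the
  # class, strongly elevated within it.
  base <- c(rep(1.0, length(subtypes) - 1), rep(NA_real_, length(classes)))
  at <- cumsum(c(0, sizes))
  mapply(function(tg, i, n, f, b) {
    list(target = tg, genes = pool[(at[i] + 1):(at[i] + n)], fold = f,
         baseline = b)
  }, targets, seq_along(targets), sizes, folds, base, SIMPLIFY = FALSE)
}

#' Simulate a ground-truth-annotated count matrix
#'
#' Draws gene-wise negative-binomial counts under the configured class and
#' subtype structure. Rare-class cell numbers are deterministic (rounded
#' expectation, minimum 2 cells whenever the configured proportion is
#' positive) so that detector benchmarks are not flaky; all other classes are
#' drawn multinomially. Identical `config` (including its seed) yields
#' bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return `list(counts = count_matrix, truth = ground truth)`. The truth is
#'   a list with `cells` (data.frame: barcode, sample, class, subtype,
#'   doublet), `programs` (named list of planted marker gene-id vectors with
#'   a `fold` attribute) and `rare_marker` (gene id).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_genes <= 0 || sum(cfg$samples) <= 0) {
    stop("configuration error: zero genes or zero cells")
  }

  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  gene_id[cfg$mito_gene_indices] <- cfg$mito_gene_names
  gene_id[cfg$rare_class$gene] <- "CALCA"

  dominant <- rownames(cfg$class_proportions)[1]
  subtypes <- names(cfg$subtype_proportions)

  with_seed(cfg$seed, {
    base_mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    for (pr in cfg$marker_programs) {
      b <- if (is.null(pr$baseline) || is.na(pr$baseline)) cfg$marker_baseline
           else pr$baseline
      base_mu[pr$genes] <- b
    }
    base_mu[cfg$rare_class$gene] <- 0          # drawn by its own rule
    mito_w <- base_mu[cfg$mito_gene_indices]
    mito_w <- mito_w / sum(mito_w)

    # per-population relative profiles over non-mito, non-rare-marker genes
    body_idx <- setdiff(seq_len(cfg$n_genes),
                        c(cfg$mito_gene_indices, cfg$rare_class$gene))
    profile_for <- function(label) {
      mu <- base_mu
      for (pr in cfg$marker_programs) {
        if (pr$target == label) mu[pr$genes] <- mu[pr$genes] * pr$fold
      }
      p <- mu[body_idx]
      p / sum(p)
    }
    pops <- c(subtypes, setdiff(rownames(cfg$class_proportions), dominant))
    profiles <- lapply(stats::setNames(pops, pops), profile_for)
    # rare-class cells transcriptionally resemble the dominant baseline
    profiles[[cfg$rare_class$class]] <- profiles[[subtypes[1]]]

    cells <- list(); trip_i <- list(); trip_j <- list(); trip_x <- list()
    col0 <- 0L
    for (s in names(cfg$samples)) {
      n <- cfg$samples[[s]]
      p_cls <- stats::setNames(cfg$class_proportions[, s],
                               rownames(cfg$class_proportions))
      rc <- cfg$rare_class$class
      n_rare <- if (rc %in% names(p_cls) && p_cls[[rc]] > 0) {
        max(2L, as.integer(round(p_cls[[rc]] * n)))
      } else 0L
      other <- setdiff(names(p_cls), rc)
      p_other <- p_cls[other]
      if (sum(p_other) <= 0) stop("configuration error: degenerate simplex")
      n_other <- as.vector(stats::rmultinom(1, n - n_rare, p_other))
      class_lab <- c(rep(other, n_other), rep(rc, n_rare))
      subtype_lab <- rep(NA_character_, n)
      is_dom <- class_lab == dominant
      subtype_lab[is_dom] <- sample(subtypes, sum(is_dom), replace = TRUE,
                                    prob = cfg$subtype_proportions)
      pop <- ifelse(is_dom, subtype_lab, class_lab)

      depth <- stats::rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog)
      depth <- pmin(pmax(depth, 400), 9000)
      mito_share <- stats::rbeta(n, cfg$mito_beta[1], cfg$mito_beta[2])

      barcode <- sprintf("c%06d-%s", col0 + seq_len(n), s)
      cells[[s]] <- data.frame(barcode = barcode, sample = s,
                               class = class_lab, subtype = subtype_lab,
                               doublet = FALSE, stringsAsFactors = FALSE)

      # draw counts in cell blocks to bound memory
      block <- 1000L
      for (b0 in seq(0L, n - 1L, by = block)) {
        idx <- (b0 + 1L):min(b0 + block, n)
        nb <- length(idx)
        mu_body <- vapply(pop[idx], function(pp) profiles[[pp]],
                          numeric(length(body_idx)))
        mu_body <- sweep(mu_body, 2, depth[idx] * (1 - mito_share[idx]), "*")
        x_body <- matrix(stats::rnbinom(length(mu_body), mu = mu_body,
                                        size = cfg$dispersion),
                         nrow = length(body_idx))
        mu_mito <- outer(mito_w, depth[idx] * mito_share[idx])
        x_mito <- matrix(stats::rnbinom(length(mu_mito), mu = mu_mito,
                                        size = cfg$dispersion),
                         nrow = length(cfg$mito_gene_indices))
        # rare-class marker: elevated Poisson in rare cells, zero-inflated
        # shifted-Poisson background elsewhere
        is_rare <- class_lab[idx] == rc
        x_marker <- integer(nb)
        x_marker[is_rare] <- stats::rpois(sum(is_rare), cfg$rare_class$mean_count)
        bg <- !is_rare & stats::runif(nb) > cfg$rare_class$zero_inflation
        x_marker[bg] <- 1L + stats::rpois(sum(bg),
                                          cfg$rare_class$background_mean - 1)
        x <- matrix(0L, nrow = cfg$n_genes, ncol = nb)
        x[body_idx, ] <- x_body
        x[cfg$mito_gene_indices, ] <- x_mito
        x[cfg$rare_class$gene, ] <- x_marker
        nz <- which(x > 0, arr.ind = TRUE)
        key <- length(trip_i) + 1L
        trip_i[[key]] <- nz[, 1]
        trip_j[[key]] <- col0 + b0 + nz[, 2]
        trip_x[[key]] <- x[nz]
      }
      col0 <- col0 + n
    }

    cells <- do.call(rbind, cells)
    rownames(cells) <- NULL
    m <- Matrix::sparseMatrix(
      i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
      dims = c(cfg$n_genes, nrow(cells)),
      dimnames = list(gene_id, cells$barcode))
    counts <- count_matrix(m, gene_name = gene_id, sample = cells$sample)

    programs <- lapply(cfg$marker_programs, function(pr) {
      structure(gene_id[pr$genes], fold = pr$fold)
    })
    names(programs) <- vapply(cfg$marker_programs, `[[`, "", "target")
    truth <- list(cells = cells, programs = programs,
                  rare_marker = gene_id[cfg$rare_class$gene],
                  rare_class = cfg$rare_class$class)
    list(counts = counts, truth = truth)
  })
}

#' Inject doublet and ambient-RNA artifacts
#'
#' Emulates the droplet artifacts that upstream cleaning tools remove:
#' doublets are formed by summing the counts of two randomly paired existing
#' cells (within the same sample) and appended as new flagged barcodes;
#' ambient contamination adds to every cell a multinomial draw from the
#' pooled gene frequency vector, sized `ambient_fraction` times that cell's
#' total.
#'
#' @param counts a [count_matrix()].
#' @param truth ground truth from [simulate_counts()].
#' @param doublet_rate,ambient_fraction rates in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return `list(counts=, truth=)` with artifacts applied and flagged.
#' @export
inject_artifacts <- function(counts, truth, doublet_rate = 0,
                             ambient_fraction = 0, seed = 1L) {
  if (doublet_rate < 0 || doublet_rate >= 1 ||
      ambient_fraction < 0 || ambient_fraction >= 1) {
    stop("configuration error: rates must lie in [0, 1)")
  }
  if (doublet_rate == 0 && ambient_fraction == 0) {
    return(list(counts = counts, truth = truth))
  }
  with_seed(seed, {
    m <- counts$m
    samp <- counts$sample
    cells <- truth$cells
    if (doublet_rate > 0) {
      n_db <- round(doublet_rate * ncol(m))
      pick <- lapply(seq_len(n_db), function(i) {
        a <- sample.int(ncol(m), 1)
        mates <- which(samp == samp[a])
        b <- if (length(mates) > 1) sample(setdiff(mates, a), 1) else a
        c(a, b)
      })
      db <- vapply(pick, function(ab) as.numeric(m[, ab[1]] + m[, ab[2]]),
                   numeric(nrow(m)))
      colnames(db) <- sprintf("dbl%05d-%s", seq_len(n_db),
                              samp[vapply(pick, `[`, 0, 1)])
      db_cells <- data.frame(
        barcode = colnames(db),
        sample = unname(samp[vapply(pick, `[`, 0, 1)]),
        class = "doublet", subtype = NA_character_, doublet = TRUE,
        stringsAsFactors = FALSE)
      m <- cbind(m, methods::as(Matrix::Matrix(db, sparse = TRUE), "generalMatrix"))
      samp <- c(samp, stats::setNames(db_cells$sample, db_cells$barcode))
      cells <- rbind(cells, db_cells)
    }
    if (ambient_fraction > 0) {
      pool <- Matrix::rowSums(m)
      pool <- pool / sum(pool)
      totals <- Matrix::colSums(m)
      add_n <- round(ambient_fraction * totals)
      amb <- vapply(add_n, function(k) {
        if (k <= 0) numeric(nrow(m)) else
          as.numeric(stats::rmultinom(1, k, pool))
      }, numeric(nrow(m)))
      m <- m + methods::as(Matrix::Matrix(amb, sparse = TRUE,
                                          dimnames = dimnames(m)), "generalMatrix")
    }
    out <- count_matrix(Matrix::drop0(m), gene_name = counts$gene_name,
                        sample = samp)
    truth$cells <- cells
    list(counts = out, truth = truth)
  })
}
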