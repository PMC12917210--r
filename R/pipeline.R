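#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: (optional) simulation, 10x reading, per-cell QC and
#' filtering, normalization, HVG selection and scaling, PCA with
#' variance-fraction component retention, SNN + Leiden clustering across the
#' resolution sweep, resolution-tree schema selection, one-vs-rest markers
#' and annotation-marker filtering, rare-cell detection, composition and
#' sample-similarity statistics, subclustering of a chosen cluster set with
#' the same operations, the fold-ratio unique-marker rule, and preranked
#' enrichment per subcluster. Every stage writes TSV artifacts under
#' `outdir` and is recorded (with timing and warnings) in a JSON run report.
#'
#' @param config path to a YAML configuration, or an equivalent named list.
#'   Recognized fields: `seed`, `outdir`, `simulate` (list passed to
#'   [simulation_config()], or `NULL`), `input` (directory for
#'   [read_tenx()], ignored when simulating), `thresholds` (named overrides
#'   for [pipeline_thresholds()]), `mito_prefix`, `rare_marker`,
#'   `subcluster` (list: `clusters` = final cluster names or `"largest"`,
#'   `exclude_samples`), `enrichment` (list: `gmt` path, `n_perm`,
#'   `weight`).
#' @return the run report (list), invisibly; also written to
#'   `outdir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(f) {
    if (is.null(config[[f]])) stop("config missing required field: ", f)
    config[[f]]
  }
  outdir <- need("outdir")
  seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t <- do.call(pipeline_thresholds,
               if (is.null(config$thresholds)) list() else config$thresholds)
  report <- list(seed = seed, thresholds = unclass(t), stages = list(),
                 warnings = character(0))
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    data.table::fwrite(as.data.frame(df), p, sep = "\t")
    p
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    ws <- character(0)
    val <- withCallingHandlers(code, warning = function(w) {
      ws <<- c(ws, conditionMessage(w)); invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2),
                                   warnings = ws)
    report$warnings <<- c(report$warnings, ws)
    val
  }

  counts <- stage("input", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- seed
      if (!is.null(args$samples)) args$samples <- unlist(args$samples)
      cfg <- do.call(simulation_config, args)
      sim <- simulate_counts(cfg)
      write_tenx(sim$counts, file.path(outdir, "simulated"), truth = sim$truth)
      report$truth_path <- file.path(outdir, "simulated", "truth.tsv")
      sim$counts
    } else {
      read_tenx(need("input"))
    }
  })

  mito <- if (is.null(config$mito_prefix)) "MT-" else config$mito_prefix
  filtered <- stage("qc", {
    qc <- compute_cell_qc(counts, mito)
    tsv(qc, "qc_per_cell.tsv")
    tsv(summarize_qc(qc), "qc_summary.tsv")
    filter_cells(counts, qc, t)
  })
  report$n_cells_input <- ncol(counts$m)
  report$n_cells_after_qc <- ncol(filtered$m)

  clustered <- stage("cluster", {
    expr <- lognormalize(filtered, t$normalize_scale)
    hvg <- select_hvgs(filtered, min(t$n_hvgs, nrow(filtered$m)))
    scl <- scale_center(expr, hvg, t$scale_clip)
    k <- min(t$n_pcs_computed, nrow(scl$mat) - 1, ncol(scl$mat) - 1)
    pca <- run_pca(scl, k, seed)
    n_pc <- retain_components(pca, t$variance_fraction)
    g <- build_snn_graph(pca, t$k_neighbors, t$snn_prune, n_dims = n_pc)
    labs <- cluster_multires(g, t$resolutions, seed)
    tree <- resolution_tree(labs)
    final <- select_schema(labs, tree, config$schema_plan)
    tsv(data.frame(barcode = names(final$labels), cluster = final$labels),
        "clusters.tsv")
    list(expr = expr, final = final, n_pc = n_pc, provenance = final$provenance)
  })
  report$n_pcs_retained <- clustered$n_pc
  report$schema <- clustered$provenance
  expr <- clustered$expr
  final <- clustered$final

  stage("markers", {
    mk <- find_all_markers(expr, final)
    tsv(mk, "markers.tsv")
    tsv(select_annotation_markers(mk, t), "annotation_markers.tsv")
  })

  rare_marker <- if (is.null(config$rare_marker)) "CALCA" else config$rare_marker
  stage("rare_cells", {
    if (rare_marker %in% rownames(filtered$m)) {
      rc <- detect_rare_cells(filtered, rare_marker, t$rare_z)
      tsv(rc$calls, "rare_cells.tsv")
      report$flagged_samples <- rc$flagged
      report$n_rare_cells <- nrow(rc$calls)
    } else {
      report$n_rare_cells <- 0L
    }
  })

  stage("similarity", {
    pt <- cluster_proportions(final, expr$sample)
    tsv(cbind(cluster = rownames(pt$counts), as.data.frame(pt$counts)),
        "cluster_counts.tsv")
    tsv(cbind(cluster = rownames(pt$pct_display), as.data.frame(pt$pct_display)),
        "cluster_percentages.tsv")
    if (length(unique(expr$sample)) >= 2) {
      cp <- correlation_matrix(pt)
      tp <- correlation_matrix(sample_expression_profile(expr))
      tsv(cbind(sample = rownames(cp), as.data.frame(cp)),
          "correlation_proportions.tsv")
      tsv(cbind(sample = rownames(tp), as.data.frame(tp)),
          "correlation_transcriptome.tsv")
    }
  })

  sub_cfg <- config$subcluster
  sub <- stage("subcluster", {
    pick <- if (is.null(sub_cfg$clusters) ||
                identical(sub_cfg$clusters, "largest")) {
      names(which.max(table(final$labels)))
    } else as.character(sub_cfg$clusters)
    cells <- names(final$labels)[final$labels %in% pick]
    if (!is.null(sub_cfg$exclude_samples)) {
      cells <- cells[!expr$sample[cells] %in% sub_cfg$exclude_samples]
    }
    if (length(cells) < 50) stop("subcluster target has fewer than 50 cells")
    subc <- subset_cells(filtered, cells)
    sexpr <- lognormalize(subc, t$normalize_scale)
    hvg <- select_hvgs(subc, min(t$n_hvgs, nrow(subc$m)))
    scl <- scale_center(sexpr, hvg, t$scale_clip)
    k <- min(t$n_pcs_computed, nrow(scl$mat) - 1, ncol(scl$mat) - 1)
    pca <- run_pca(scl, k, seed)
    n_pc <- retain_components(pca, t$variance_fraction)
    g <- build_snn_graph(pca, min(t$k_neighbors, length(cells) - 1),
                         t$snn_prune, n_dims = n_pc)
    labs <- cluster_multires(g, t$resolutions, seed)
    sfinal <- select_schema(labs, resolution_tree(labs))
    tsv(data.frame(barcode = names(sfinal$labels), cluster = sfinal$labels),
        "subclusters.tsv")
    uniq <- unique_fold_markers(sexpr, sfinal, t$unique_fold, t$unique_floor)
    tsv(data.frame(cluster = rep(names(uniq), lengths(uniq)),
                   gene = unlist(uniq)), "subcluster_unique_markers.tsv")
    qs <- compute_cell_qc(subc, mito)
    tsv(summarize_qc(qs, sfinal$labels[qs$barcode]), "subcluster_qc.tsv")
    report$n_subclusters <- length(unique(sfinal$labels))
    list(expr = sexpr, final = sfinal, n_pc = n_pc)
  })

  if (!is.null(sub) && !is.null(config$enrichment$gmt)) {
    stage("enrichment", {
      sets <- read_gmt(config$enrichment$gmt)
      n_perm <- if (is.null(config$enrichment$n_perm)) 1000 else
        config$enrichment$n_perm
      wgt <- if (is.null(config$enrichment$weight)) 1 else
        config$enrichment$weight
      per <- list()
      for (cl in sort(unique(sub$final$labels))) {
        rk <- rank_by_z(sub$expr, sub$final, cl)
        per[[cl]] <- permutation_pvalues(rk, sets, n_perm, wgt, seed,
                                         t$gsea_max_padj)
      }
      all_rec <- do.call(rbind, lapply(names(per), function(cl) {
        cbind(cluster = cl, per[[cl]])
      }))
      tsv(all_rec, "enrichment.tsv")
      if (length(per) >= 2) {
        su <- shared_unique_pathways(per, t$gsea_max_padj)
        tsv(data.frame(kind = c(rep("shared", length(su$shared)),
                                rep(names(su$unique), lengths(su$unique))),
                       set = c(su$shared, unlist(su$unique))),
            "pathways_shared_unique.tsv")
        report$n_shared_pathways <- length(su$shared)
      }
    })
  }

  report$outputs <- list.files(outdir, recursive = TRUE)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
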