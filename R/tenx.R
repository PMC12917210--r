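#' Write a count matrix as 10x-style triplet directories
#'
#' Emits one triplet directory per sample under `directory`
#' (`<sample>/matrix.mtx`, `features.tsv`, `barcodes.tsv`), MatrixMarket
#' coordinate *integer* with genes as rows. When ground truth is supplied it
#' is serialized alongside as `truth.tsv` keyed by barcode (a sidecar, never
#' embedded in the matrix). Round-trips losslessly through [read_tenx()].
#'
#' @param counts a [count_matrix()].
#' @param directory output directory (created if missing).
#' @param truth optional ground truth from [simulate_counts()].
#' @param gzip write `.gz`-compressed triplet files.
#' @return (invisibly) character vector of the per-sample directories.
#' @export
write_tenx <- function(counts, directory, truth = NULL, gzip = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  ext <- if (gzip) ".gz" else ""
  dirs <- character(0)
  for (s in unique(counts$sample)) {
    sub <- subset_cells(counts, names(counts$sample)[counts$sample == s])
    d <- file.path(directory, s)
    dir.create(d, showWarnings = FALSE)
    m <- sub$m
    mtx_path <- file.path(d, paste0("matrix.mtx", ext))
    con <- if (gzip) gzfile(mtx_path, "w") else file(mtx_path, "w")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
    close(con)
    if (length(m@x)) {
      tm <- methods::as(m, "TsparseMatrix")
      trip <- data.frame(i = tm@i + 1L, j = tm@j + 1L, x = as.integer(tm@x))
      trip <- trip[order(trip$j, trip$i), ]
      data.table::fwrite(trip, mtx_path, sep = " ", col.names = FALSE,
                         append = TRUE)
    }
    data.table::fwrite(
      data.table::data.table(id = rownames(m), name = sub$gene_name,
                             type = "Gene Expression"),
      file.path(d, paste0("features.tsv", ext)),
      sep = "\t", col.names = FALSE)
    data.table::fwrite(data.table::data.table(barcode = colnames(m)),
                       file.path(d, paste0("barcodes.tsv", ext)),
                       sep = "\t", col.names = FALSE)
    dirs <- c(dirs, d)
  }
  if (!is.null(truth)) {
    data.table::fwrite(truth$cells, file.path(directory, "truth.tsv"),
                       sep = "\t")
  }
  invisible(dirs)
}

# headerless TSV reader that transparently handles .gz
read_tsv_plain <- function(path) {
  lines <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  k <- max(lengths(parts))
  as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- k
    p
  })), stringsAsFactors = FALSE)
}

tenx_file <- function(dir, stem) {
  for (f in file.path(dir, c(stem, paste0(stem, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("missing ", stem, " in ", dir)
}

read_tenx_one <- function(dir) {
  mtx <- tenx_file(dir, "matrix.mtx")
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else file(mtx)
  m <- Matrix::readMM(con)
  if (length(m@x) && any(m@x != round(m@x) | m@x < 0)) {
    stop("format error: non-integer or negative entries in ", mtx)
  }
  feats <- read_tsv_plain(tenx_file(dir, "features.tsv"))
  bcs <- read_tsv_plain(tenx_file(dir, "barcodes.tsv"))[[1]]
  if (nrow(feats) != nrow(m) || length(bcs) != ncol(m)) {
    stop("format error: MTX header dimensions (", nrow(m), " x ", ncol(m),
         ") do not match features/barcodes files in ", dir)
  }
  if (anyDuplicated(bcs)) stop("format error: duplicate barcodes in ", dir)
  dimnames(m) <- list(feats[[1]], bcs)
  # sample id taken from the barcode suffix ("...-<sample>"), else dir name
  suff <- sub("^.*-", "", bcs)
  samp <- if (all(grepl("-", bcs))) suff else rep(basename(dir), length(bcs))
  list(m = methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
       gene_name = if (ncol(feats) >= 2) feats[[2]] else feats[[1]],
       sample = samp)
}

#' Read 10x-style triplets into a count matrix
#'
#' `directory` may be a single triplet directory or a parent directory whose
#' subdirectories each hold one sample's triplet (the layout written by
#' [write_tenx()]); in the latter case samples are concatenated in sorted
#' subdirectory order. Plain and gzipped triplets are both accepted.
#'
#' @param directory path.
#' @return a [count_matrix()]; gene and barcode order preserved from files.
#' @export
read_tenx <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  has_triplet <- file.exists(file.path(directory, "matrix.mtx")) ||
    file.exists(file.path(directory, "matrix.mtx.gz"))
  if (has_triplet) {
    p <- read_tenx_one(directory)
    return(count_matrix(p$m, gene_name = p$gene_name, sample = p$sample))
  }
  subs <- sort(list.dirs(directory, recursive = FALSE))
  subs <- subs[file.exists(file.path(subs, "matrix.mtx")) |
                 file.exists(file.path(subs, "matrix.mtx.gz"))]
  if (!length(subs)) stop("no 10x triplets found under ", directory)
  parts <- lapply(subs, read_tenx_one)
  ids <- lapply(parts, function(p) rownames(p$m))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    stop("format error: samples disagree on the feature list")
  }
  m <- do.call(cbind, lapply(parts, `[[`, "m"))
  count_matrix(m, gene_name = parts[[1]]$gene_name,
               sample = unlist(lapply(parts, `[[`, "sample")))
}

#' Read a ground-truth sidecar written by [write_tenx()]
#' @param directory the parent directory given to [write_tenx()].
#' @return data.frame keyed by barcode.
#' @export
read_truth <- function(directory) {
  f <- file.path(directory, "truth.tsv")
  if (!file.exists(f)) stop("no truth.tsv in ", directory)
  as.data.frame(data.table::fread(f, sep = "\t"))
}
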