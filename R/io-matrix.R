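#' Read a cell x guide (or cell x gene) UMI count matrix
#'
#' Reads either the CellRanger-style Matrix Market triplet layout (features as
#' rows, cells as columns, plus `barcodes.tsv` and `features.tsv`; plain or
#' gzipped) or a dense CSV whose header row carries the feature ids and whose
#' first column carries the cell barcodes. The returned matrix is always
#' oriented cells x features as a sparse `dgCMatrix` with unique dimnames.
#'
#' @param matrix_path Path to a `.mtx`/`.mtx.gz` file or a `.csv` file.
#' @param barcodes_path,features_path Paths to the barcode and feature TSVs
#'   (first column used); required for the Matrix Market layout, ignored for
#'   CSV.
#' @return Sparse `dgCMatrix`, cells as rows, features as columns.
#' @export
read_guide_matrix <- function(matrix_path, barcodes_path = NULL,
                              features_path = NULL) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (grepl("\\.csv(\\.gz)?$", matrix_path)) {
    df <- utils::read.csv(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    cells <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(cells, colnames(df)[-1L])
    counts <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")
  } else {
    if (is.null(barcodes_path) || is.null(features_path)) {
      stop("barcodes_path and features_path are required for Matrix Market input")
    }
    mm <- Matrix::readMM(matrix_path)
    barcodes <- .read_id_column(barcodes_path)
    features <- .read_id_column(features_path)
    if (nrow(mm) != length(features) || ncol(mm) != length(barcodes)) {
      stop(sprintf(
        "matrix dimensions (%d features x %d cells) do not match %d features / %d barcodes",
        nrow(mm), ncol(mm), length(features), length(barcodes)))
    }
    dimnames(mm) <- list(features, barcodes)
    counts <- methods::as(methods::as(Matrix::t(mm), "generalMatrix"),
                          "CsparseMatrix")
  }
  validate_count_matrix(counts)
  counts
}

#' @rdname read_guide_matrix
#' @export
read_expression_matrix <- read_guide_matrix

.read_id_column <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
  as.character(ids)
}

#' Validate a cells x features count matrix
#'
#' Checks the invariants every matrix in the pipeline must satisfy: unique
#' non-empty cell and feature identifiers, non-negative counts, at least one
#' feature column.
#'
#' @param counts Matrix-like object, cells x features, with dimnames.
#' @return Invisibly `counts`; errors otherwise.
#' @export
validate_count_matrix <- function(counts) {
  dn <- dimnames(counts)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]])) {
    stop("count matrix must carry cell and feature identifiers as dimnames")
  }
  if (anyDuplicated(dn[[1L]])) stop("duplicate cell barcodes in count matrix")
  if (anyDuplicated(dn[[2L]])) stop("duplicate feature identifiers in count matrix")
  if (ncol(counts) < 1L) stop("count matrix must have at least one feature")
  if (min(counts) < 0) stop("count matrix has negative entries")
  invisible(counts)
}

#' Write a count matrix in CellRanger Matrix Market layout
#'
#' Writes `matrix.mtx` (features x cells), `barcodes.tsv` and `features.tsv`
#' into `dir`. The on-disk orientation follows the CellRanger convention;
#' [read_guide_matrix()] transposes back, so write -> read round-trips
#' bit-exactly.
#'
#' @param counts Cells x features matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_guide_matrix <- function(counts, dir) {
  validate_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(methods::as(Matrix::t(counts), "CsparseMatrix"), paths[1L])
  writeLines(rownames(counts), paths[2L])
  writeLines(colnames(counts), paths[3L])
  invisible(paths)
}

#' Write a count matrix as dense CSV
#'
#' Header row = feature ids, first column = cell barcodes; the dialect
#' [read_guide_matrix()] accepts.
#'
#' @inheritParams write_guide_matrix
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_matrix_csv <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(cell_id = rownames(counts),
                   as.matrix(counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Saturation-curve (knee) filtering of one cell's guide UMIs
#'
#' Separates a cell's genuinely expressed sgRNAs from ambient background by
#' the knee of its ranked cumulative UMI curve. Guides are sorted by UMI count
#' descending (ties broken by guide identifier); the cumulative UMI fraction
#' is compared against the straight line joining the curve's endpoints, and
#' the guide index maximizing the distance to that chord is the knee. All
#' guides up to the knee are retained, plus any guide tied with the knee's UMI
#' value, so the result is independent of input ordering. Zero-UMI guides are
#' never retained; an all-zero cell yields an empty set.
#'
#' @param cell_counts Named non-negative vector of UMI counts over the guide
#'   library for one cell (names are guide ids).
#' @param method `"knee"` (default) or a function `f(sorted_umis)` returning
#'   the number of guides to retain from a UMI-descending vector, for plugging
#'   in an alternative detector.
#' @return List with elements `guides` (character vector of retained guide
#'   ids, UMI-descending) and `umis` (their counts).
#' @export
filter_umi_saturation <- function(cell_counts, method = "knee") {
  if (is.null(names(cell_counts))) {
    names(cell_counts) <- paste0("g", seq_along(cell_counts))
  }
  pos <- cell_counts[cell_counts > 0]
  if (length(pos) == 0L) {
    return(list(guides = character(0), umis = numeric(0)))
  }
  ord <- order(-pos, names(pos))
  u <- as.numeric(pos[ord])
  keep <- if (is.function(method)) method(u) else .knee_index(u)
  keep <- max(keep, 1L)
  # retain every guide tied with the knee's UMI value
  keep <- sum(u >= u[keep])
  list(guides = names(pos)[ord][seq_len(keep)], umis = u[seq_len(keep)])
}

# index of maximal distance between the cumulative UMI fraction curve
# (prepended with the origin) and the chord joining its endpoints
.knee_index <- function(u) {
  G <- length(u)
  if (G <= 1L) return(G)
  y <- cumsum(u) / sum(u)        # y_i at x_i = i/G; chord from (0,0) to (1,1)
  which.max(y - seq_len(G) / G)
}

#' Detect guides in every cell of a matrix
#'
#' Applies [filter_umi_saturation()] to each cell of a cells x guides UMI
#' matrix and collects the detected sets. Cells with zero detected guides are
#' carried through with empty sets (and counted in the summary), never
#' dropped silently.
#'
#' @param counts Cells x guides sparse matrix with dimnames.
#' @param method Passed to [filter_umi_saturation()].
#' @return A [guide_sets] object.
#' @export
detect_guides <- function(counts, method = "knee") {
  validate_count_matrix(counts)
  cm <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  tm <- Matrix::t(cm)  # guides x cells: cheap per-cell column access
  p <- tm@p
  ids <- colnames(counts)
  guides <- vector("list", ncol(tm))
  umis <- vector("list", ncol(tm))
  for (j in seq_len(ncol(tm))) {
    rng <- if (p[j + 1L] > p[j]) (p[j] + 1L):p[j + 1L] else integer(0)
    v <- tm@x[rng]
    names(v) <- ids[tm@i[rng] + 1L]
    gs <- filter_umi_saturation(v, method = method)
    guides[[j]] <- match(gs$guides, ids)
    umis[[j]] <- gs$umis
  }
  guide_sets(cell_id = rownames(counts), guide_ids = ids,
             guides = guides, umis = umis)
}

#' Container for per-cell detected guide sets
#'
#' @param cell_id Character vector of cell barcodes.
#' @param guide_ids Character vector of the full guide library (its length is
#'   the library size `M`).
#' @param guides List (one element per cell) of integer indices into
#'   `guide_ids`.
#' @param umis List of per-guide UMI counts parallel to `guides`.
#' @return Object of class `guide_sets`.
#' @export
guide_sets <- function(cell_id, guide_ids, guides, umis) {
  stopifnot(length(cell_id) == length(guides),
            length(guides) == length(umis),
            !anyDuplicated(cell_id), !anyDuplicated(guide_ids))
  if (length(guides) &&
      any(vapply(guides, function(g) length(g) &&
                   (min(g) < 1L || max(g) > length(guide_ids)), FALSE))) {
    stop("guide indices outside the library")
  }
  structure(list(cell_id = as.character(cell_id),
                 guide_ids = as.character(guide_ids),
                 guides = guides, umis = umis),
            class = "guide_sets")
}

#' @export
print.guide_sets <- function(x, ...) {
  k <- lengths(x$guides)
  cat(sprintf("guide_sets: %d cells over a library of %d sgRNAs\n",
              length(x$cell_id), length(x$guide_ids)))
  if (length(k)) {
    cat(sprintf("  guides/cell: mean %.1f, median %s; %d cells with empty sets\n",
                mean(k), stats::median(k), sum(k == 0L)))
  }
  invisible(x)
}

#' Extract one cell's detected guide ids
#'
#' @param sets A [guide_sets] object.
#' @param cell Cell barcode.
#' @return Character vector of guide ids.
#' @export
guides_of <- function(sets, cell) {
  i <- match(cell, sets$cell_id)
  if (is.na(i)) stop("unknown cell id: ", cell)
  sets$guide_ids[sets$guides[[i]]]
}

#' Per-cell guide detection summary
#'
#' Mean and median detected guides per cell and the mean UMI per detected
#' guide, the metrics used to judge guide-capture quality. An empty
#' population (or one with no detected guides) reports `NA`, not zero.
#'
#' @param sets A [guide_sets] object.
#' @return List with `n_cells`, `mean_guides_per_cell`,
#'   `median_guides_per_cell`, `mean_umi_per_guide`.
#' @export
guide_detection_stats <- function(sets) {
  stopifnot(inherits(sets, "guide_sets"))
  k <- lengths(sets$guides)
  allu <- unlist(sets$umis, use.names = FALSE)
  list(
    n_cells = length(k),
    mean_guides_per_cell = if (length(k)) mean(k) else NA_real_,
    median_guides_per_cell = if (length(k)) stats::median(k) else NA_real_,
    mean_umi_per_guide = if (length(allu)) mean(allu) else NA_real_
  )
}
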