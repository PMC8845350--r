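#' Counts-per-million normalization
#'
#' Scales each cell's counts to sum to one million, removing sequencing-depth
#' differences before z-scoring. Cells with zero total counts cannot be
#' normalized and are excluded with a warning.
#'
#' @param counts Cells x genes matrix with dimnames.
#' @return Sparse cells x genes CPM matrix (each row sums to 1e6).
#' @export
cpm_normalize <- function(counts) {
  validate_count_matrix(counts)
  depth <- Matrix::rowSums(counts)
  if (any(depth == 0)) {
    warning(sum(depth == 0), " zero-depth cell(s) excluded from CPM normalization")
    counts <- counts[depth > 0, , drop = FALSE]
    depth <- depth[depth > 0]
  }
  out <- Matrix::Diagonal(x = 1e6 / depth) %*% counts
  dimnames(out) <- dimnames(counts)
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Filter genes expressed in too few cells
#'
#' Keeps genes with a nonzero count in at least `min_cell_fraction` of cells
#' (the boundary fraction is kept), focusing downstream z-score profiles on
#' genes with robust signal.
#'
#' @param counts Cells x genes count matrix.
#' @param min_cell_fraction Minimum expressing-cell fraction in `(0, 1]`
#'   (default 0.10).
#' @return The column-subset matrix.
#' @export
filter_low_expressed <- function(counts, min_cell_fraction = 0.10) {
  validate_count_matrix(counts)
  if (min_cell_fraction <= 0 || min_cell_fraction > 1) {
    stop("min_cell_fraction must be in (0, 1]")
  }
  frac <- Matrix::colMeans(counts > 0)
  keep <- frac >= min_cell_fraction
  if (!any(keep)) stop("no genes pass the expression filter")
  counts[, keep, drop = FALSE]
}

#' Per-gene expression z-scores across cells
#'
#' For each gene, centers and scales its values across all cells using the
#' sample standard deviation (denominator `n - 1`). Genes with zero variance
#' cannot be standardized and are excluded with a warning rather than
#' propagating `NaN`s.
#'
#' @param cpm Cells x genes (typically CPM-normalized) matrix; needs >= 2
#'   cells.
#' @return Dense cells x genes matrix of z-scores; every column has mean 0
#'   and sample sd 1.
#' @export
gene_zscore <- function(cpm) {
  if (nrow(cpm) < 2L) stop("z-scores need at least 2 cells")
  m <- as.matrix(cpm)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  zero <- sd == 0 | is.na(sd)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) excluded from z-scoring")
    m <- m[, !zero, drop = FALSE]
    mu <- mu[!zero]
    sd <- sd[!zero]
  }
  if (ncol(m) == 0L) stop("no genes with positive variance")
  scale(m, center = mu, scale = sd)[, , drop = FALSE]
}

#' Chromosomally ordered per-clone copy-number profiles
#'
#' Orders genes along the genome (chromosome rank, then start), and averages
#' each clone's z-scores per gene. Runs of positive mean z-scores over
#' contiguous genes suggest segmental copy-number gain in that clone; runs of
#' negative values suggest loss. Clones with fewer than `min_cells` members
#' get a profile but are flagged low-confidence.
#'
#' @param z Cells x genes z-score matrix (see [gene_zscore()]).
#' @param assignment A `clone_assignment` covering the rows of `z`, or a
#'   named vector/factor of clone labels per cell (`NA` = unassigned).
#' @param annotation A `gene_annotation`; genes of `z` absent from it are
#'   dropped with a warning.
#' @param min_cells Low-confidence threshold (default 2).
#' @return `cnv_profile`: list with `genes` (ordered annotation subset), `z`
#'   (cells x ordered genes), `profiles` (clones x genes mean z),
#'   `clone_sizes`, `low_confidence`, `boundaries` (last gene index per
#'   chromosome, for heatmap guides).
#' @export
clone_mean_profile <- function(z, assignment, annotation, min_cells = 2L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  labels <- if (inherits(assignment, "clone_assignment")) {
    stats::setNames(ifelse(assignment$is_doublet, NA_character_,
                           paste0("clone_", assignment$clone)),
                    assignment$cell_id)
  } else {
    stats::setNames(as.character(assignment), names(assignment))
  }
  labels <- labels[rownames(z)]
  keep_genes <- colnames(z)[colnames(z) %in% annotation$gene_id]
  if (length(keep_genes) < ncol(z)) {
    warning(ncol(z) - length(keep_genes),
            " gene(s) absent from the annotation dropped from the profile")
  }
  ann <- annotation[match(keep_genes, annotation$gene_id), , drop = FALSE]
  ord <- order(.chrom_rank(ann$chrom, attr(annotation, "chromosome_order")),
               ann$start, ann$gene_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  zz <- z[, ann$gene_id, drop = FALSE]
  cells <- !is.na(labels)
  lab <- labels[cells]
  prof <- rowsum(zz[cells, , drop = FALSE], lab) / as.vector(table(lab))
  sizes <- as.vector(table(lab))
  names(sizes) <- rownames(prof)
  runs <- rle(ann$chrom)
  structure(list(
    genes = ann,
    z = zz,
    profiles = prof,
    clone_sizes = sizes,
    low_confidence = sizes < min_cells,
    boundaries = stats::setNames(cumsum(runs$lengths), runs$values)
  ), class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf(paste0("cnv_profile: %d clones x %d genes over %d chromosomes\n",
                     "  mean |profile z| = %.3f\n"),
              nrow(x$profiles), ncol(x$profiles), length(x$boundaries),
              mean(abs(x$profiles))))
  invisible(x)
}

#' Exploratory segment calls from a copy-number profile
#'
#' Flags runs where a centered rolling mean of a clone's z-profile crosses a
#' cutoff, as candidate gains (positive) or losses (negative). This is a
#' visual aid for picking regions to inspect, not a statistical CNV caller.
#'
#' @param profile A [clone_mean_profile()] result.
#' @param window Rolling window in genes (odd; default 25).
#' @param cutoff Absolute mean-z cutoff (default 0.3).
#' @return `data.frame` with `clone`, `chrom`, `start`, `end` (coordinates of
#'   the first/last gene in the run), `n_genes`, `mean_z`, `direction`.
#' @export
call_cnv_segments <- function(profile, window = 25L, cutoff = 0.3) {
  stopifnot(inherits(profile, "cnv_profile"))
  window <- max(3L, window %/% 2L * 2L + 1L)
  ann <- profile$genes
  out <- list()
  for (cl in rownames(profile$profiles)) {
    v <- profile$profiles[cl, ]
    for (chrom in names(profile$boundaries)) {
      idx <- which(ann$chrom == chrom)
      if (length(idx) < window) next
      rm_ <- as.vector(stats::filter(v[idx], rep(1 / window, window)))
      hit <- !is.na(rm_) & abs(rm_) > cutoff
      if (!any(hit)) next
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (seg in which(r$values)) {
        sel <- idx[starts[seg]:ends[seg]]
        out[[length(out) + 1L]] <- data.frame(
          clone = cl, chrom = chrom,
          start = ann$start[sel[1L]], end = ann$end[sel[length(sel)]],
          n_genes = length(sel), mean_z = mean(v[sel]),
          direction = if (mean(v[sel]) > 0) "gain" else "loss",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(clone = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_genes = integer(0), mean_z = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Overlap candidate segments with labeled genes
#'
#' Reports which user-labeled genes (e.g. oncogenes and tumor suppressors)
#' fall inside candidate copy-number segments, with the segment's mean
#' z-score, so amplifications over oncogenes / deletions over suppressors can
#' be read off directly.
#'
#' @param profile A [clone_mean_profile()] result (supplies coordinates).
#' @param segments `data.frame` as returned by [call_cnv_segments()] (or
#'   user-supplied with columns `clone`, `chrom`, `start`, `end`, `mean_z`).
#' @param labeled_genes `data.frame` with columns `gene_id`, `label`.
#' @return `data.frame` with one row per (segment, overlapping labeled gene).
#' @export
overlap_labeled_genes <- function(profile, segments, labeled_genes) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!nrow(labeled_genes) || !nrow(segments)) {
    return(data.frame(clone = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      mean_z = numeric(0), gene_id = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ann <- profile$genes
  unknown <- setdiff(labeled_genes$gene_id, ann$gene_id)
  if (length(unknown)) {
    warning("labeled gene(s) not in the profile: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  lg <- merge(labeled_genes, ann, by = "gene_id")
  out <- list()
  for (s in seq_len(nrow(segments))) {
    hit <- lg$chrom == segments$chrom[s] &
      lg$start >= segments$start[s] & lg$start < segments$end[s]
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        clone = segments$clone[s], chrom = segments$chrom[s],
        start = segments$start[s], end = segments$end[s],
        mean_z = segments$mean_z[s],
        gene_id = lg$gene_id[hit], label = lg$label[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(clone = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      mean_z = numeric(0), gene_id = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Heatmap of clone copy-number profiles
#'
#' Clones as rows, chromosomally ordered genes as columns, with chromosome
#' boundaries marked. Z-values are clipped at `clip` for display only.
#'
#' @param profile A [clone_mean_profile()] result.
#' @param clip Display clip on |z| (default 2).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `profile`.
#' @export
plot_cnv_heatmap <- function(profile, clip = 2, ...) {
  z <- pmin(pmax(profile$profiles, -clip), clip)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(51)
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)),
                  z = t(z), col = pal, zlim = c(-clip, clip), axes = FALSE,
                  xlab = "genes (chromosomal order)", ylab = "clone", ...)
  graphics::abline(v = profile$boundaries + 0.5, col = "grey40", lwd = 0.5)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(profile)
}
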