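#' Read an sgRNA -> target-region map
#'
#' Two-column TSV (guide id, region id), with or without a header line.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `guide_id`, `region_id`.
#' @export
read_region_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("region map needs two columns: guide_id, region_id")
  if (identical(tolower(df[1L, 1L]), "guide_id")) df <- df[-1L, , drop = FALSE]
  data.frame(guide_id = as.character(df[[1L]]),
             region_id = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Group cells by perturbed target region
#'
#' A cell belongs to a region's group when it carries at least one detected
#' sgRNA mapped to that region; a cell with guides from several regions
#' belongs to all of them. Regions with zero carrying cells are reported and
#' kept as empty groups (downstream analyses skip them).
#'
#' @param region_map `data.frame` with columns `guide_id`, `region_id` (see
#'   [read_region_map()]); every guide must exist in the library.
#' @param sets A [guide_sets] object.
#' @return Named list: region id -> character vector of cell ids.
#' @export
cells_for_region <- function(region_map, sets) {
  stopifnot(inherits(sets, "guide_sets"))
  miss <- setdiff(region_map$guide_id, sets$guide_ids)
  if (length(miss)) {
    stop("region map guide(s) absent from the library: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  gidx <- match(region_map$guide_id, sets$guide_ids)
  regions <- split(gidx, region_map$region_id)
  out <- lapply(regions, function(g) {
    sets$cell_id[vapply(sets$guides, function(cg) any(cg %in% g), FALSE)]
  })
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty)) {
    message("region(s) with no carrying cells: ", paste(empty, collapse = ", "))
  }
  out
}

#' Significance of the cell overlap between two region groups
#'
#' Hypergeometric survival p-value of the observed number of shared cells
#' given the two group sizes and the size of the cell universe — the same
#' overlap test applied to cells instead of guides. Large shared-cell counts
#' between supposedly independent perturbations are the signature of a clone
#' spanning both regions.
#'
#' @param cells_a,cells_b Character vectors of cell ids.
#' @param universe All cell ids (or its size) both groups are drawn from.
#' @return List with `overlap`, `n_a`, `n_b`, `n_universe`, `log10_p`.
#' @export
region_overlap_significance <- function(cells_a, cells_b, universe) {
  n_univ <- if (is.numeric(universe) && length(universe) == 1L) universe
            else length(unique(universe))
  cells_a <- unique(cells_a)
  cells_b <- unique(cells_b)
  if (length(cells_a) > n_univ || length(cells_b) > n_univ) {
    stop("group larger than the cell universe")
  }
  ov <- sum(cells_a %in% cells_b)
  list(overlap = ov, n_a = length(cells_a), n_b = length(cells_b),
       n_universe = n_univ,
       log10_p = overlap_log10_pvalue(ov, n_univ, length(cells_a),
                                      length(cells_b)))
}

# two-tailed hypergeometric log10 p-values on UMI draws, vectorized over
# genes: universe = all UMIs, marked = the gene's UMIs, drawn = UMIs in the
# cell group, observed = the gene's UMIs in the group.
.de_log10p <- function(x, gene_tot, grp_tot, all_tot) {
  down <- stats::phyper(x, gene_tot, all_tot - gene_tot, grp_tot,
                        lower.tail = TRUE, log.p = TRUE) / log(10)
  up <- stats::phyper(x - 1, gene_tot, all_tot - gene_tot, grp_tot,
                      lower.tail = FALSE, log.p = TRUE) / log(10)
  list(down = down, up = up)
}

#' Observed differential-expression p-values for one cell group
#'
#' For every gene, tests whether its UMI share inside the group deviates from
#' its share in all cells, as a hypergeometric draw of the group's total UMIs
#' from the summed UMI pool: the depletion tail gives the down-regulation
#' p-value, the enrichment tail the up-regulation p-value, and the smaller
#' tail sets the reported direction. Genes with zero total UMIs are excluded.
#'
#' @param expr Cells x genes count matrix.
#' @param group_cells Cell ids of the (nonempty) group.
#' @return `data.frame` with `gene_id`, `direction` (`"up"`/`"down"`),
#'   `log10_p` (the directional tail), `log10_p_down`, `log10_p_up`.
#' @export
gene_observed_pvalue <- function(expr, group_cells) {
  validate_count_matrix(expr)
  if (!length(group_cells)) stop("empty cell group")
  if (!all(group_cells %in% rownames(expr))) stop("unknown cells in group")
  gene_tot <- Matrix::colSums(expr)
  keep <- gene_tot > 0
  if (!all(keep)) expr <- expr[, keep, drop = FALSE]
  gene_tot <- gene_tot[keep]
  all_tot <- sum(gene_tot)
  x <- Matrix::colSums(expr[group_cells, , drop = FALSE])
  grp_tot <- sum(x)
  lp <- .de_log10p(x, gene_tot, grp_tot, all_tot)
  up <- lp$up < lp$down
  data.frame(gene_id = colnames(expr),
             direction = ifelse(up, "up", "down"),
             log10_p = pmin(lp$down, lp$up),
             log10_p_down = lp$down, log10_p_up = lp$up,
             stringsAsFactors = FALSE)
}

#' Randomized background p-values for a group size
#'
#' Repeats the observed-p-value computation for random cell groups of the
#' same size (emulating random sgRNA combinations) and summarizes the
#' directional (smaller-tail) log10 p per gene. The background captures how
#' significant a gene looks for *any* group of that size — clonal structure,
#' expression skew — so subtracting it from the observed value cancels
#' signal not caused by the perturbation.
#'
#' @param expr Cells x genes count matrix.
#' @param group_size Number of cells per random group.
#' @param n_randomizations Number of random groups (default 10000; reduced
#'   values trade precision for speed).
#' @param summary `"mean"` (default) or `"median"` of the randomized log10 p.
#' @param seed Seed (local RNG); identical seeds give identical backgrounds.
#' @return Numeric vector of background log10 p per gene (genes with zero
#'   total UMIs excluded, matching [gene_observed_pvalue()]).
#' @export
background_pvalues <- function(expr, group_size, n_randomizations = 10000,
                               summary = c("mean", "median"), seed = 1) {
  summary <- match.arg(summary)
  validate_count_matrix(expr)
  if (n_randomizations < 1) stop("need at least one randomization")
  if (group_size > nrow(expr)) stop("group size exceeds the cell universe")
  gene_tot <- Matrix::colSums(expr)
  keep <- gene_tot > 0
  expr <- expr[, keep, drop = FALSE]
  gene_tot <- gene_tot[keep]
  all_tot <- sum(gene_tot)
  .with_local_seed(seed, {
    acc <- if (summary == "mean") numeric(ncol(expr)) else
      matrix(0, n_randomizations, ncol(expr))
    for (b in seq_len(n_randomizations)) {
      cells <- sample.int(nrow(expr), group_size)
      x <- Matrix::colSums(expr[cells, , drop = FALSE])
      lp <- .de_log10p(x, gene_tot, sum(x), all_tot)
      v <- pmin(lp$down, lp$up)
      if (summary == "mean") acc <- acc + v else acc[b, ] <- v
    }
    bg <- if (summary == "mean") acc / n_randomizations else
      apply(acc, 2L, stats::median)
    stats::setNames(bg, colnames(expr))
  })
}

#' Region-level differential expression with Significance Scores
#'
#' For each requested region: computes observed directional p-values for the
#' region's cell group, a randomized background of matched group size, and
#' the Significance Score = observed log10 p minus background log10 p. Strong
#' negative scores mark genes whose expression shift in the region's cells
#' exceeds what arbitrary groups of that size produce. The `signed_score`
#' column flips the sign for up-regulated genes so that Manhattan-style plots
#' show down-regulation below zero and up-regulation above.
#'
#' @param expr Cells x genes count matrix (the cell universe; subset it first
#'   to exclude clonal cells or restrict to one clone).
#' @param region_cells Named list region -> cell ids (see
#'   [cells_for_region()]); empty regions are skipped with a message.
#' @param n_randomizations,summary,seed Passed to [background_pvalues()];
#'   regions of equal size share one background.
#' @return `region_de`: `data.frame` with `region_id`, `gene_id`,
#'   `direction`, `obs_log10p`, `bg_log10p`, `sig_score`, `signed_score`,
#'   `n_region_cells`.
#' @export
region_de <- function(expr, region_cells, n_randomizations = 10000,
                      summary = c("mean", "median"), seed = 1) {
  summary <- match.arg(summary)
  if (!length(region_cells)) stop("no regions given")
  use <- lengths(region_cells) > 0L
  if (!all(use)) {
    message("skipping empty region(s): ",
            paste(names(region_cells)[!use], collapse = ", "))
  }
  region_cells <- region_cells[use]
  bg_cache <- list()
  out <- lapply(names(region_cells), function(rg) {
    cells <- intersect(region_cells[[rg]], rownames(expr))
    if (!length(cells)) return(NULL)
    obs <- gene_observed_pvalue(expr, cells)
    key <- as.character(length(cells))
    if (is.null(bg_cache[[key]])) {
      bg_cache[[key]] <<- background_pvalues(
        expr, length(cells), n_randomizations = n_randomizations,
        summary = summary, seed = seed)
    }
    bg <- bg_cache[[key]][obs$gene_id]
    score <- obs$log10_p - bg
    data.frame(region_id = rg, gene_id = obs$gene_id,
               direction = obs$direction,
               obs_log10p = obs$log10_p, bg_log10p = unname(bg),
               sig_score = score,
               signed_score = ifelse(obs$direction == "down", score, -score),
               n_region_cells = length(cells),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  structure(res, n_randomizations = n_randomizations, summary = summary,
            seed = seed, class = c("region_de", "data.frame"))
}

#' Chromosomally ordered Significance Score table
#'
#' Joins region-level DE results with gene coordinates and orders genes along
#' the genome, the layout of a Manhattan plot (signed score: positive =
#' up-regulated, negative = down-regulated).
#'
#' @param results A [region_de()] result.
#' @param annotation A `gene_annotation` covering the result genes.
#' @return `data.frame` ordered by (region, chromosome rank, start) with the
#'   annotation columns appended.
#' @export
manhattan_table <- function(results, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (is.null(results) || !nrow(results)) {
    return(data.frame(region_id = character(0), gene_id = character(0),
                      chrom = character(0), start = numeric(0),
                      signed_score = numeric(0), stringsAsFactors = FALSE))
  }
  m <- match(results$gene_id, annotation$gene_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " result gene(s) absent from the annotation dropped")
    results <- results[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  df <- cbind(results,
              annotation[m, c("chrom", "start"), drop = FALSE])
  rank <- .chrom_rank(df$chrom, attr(annotation, "chromosome_order"))
  df <- df[order(df$region_id, rank, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Manhattan plot of Significance Scores
#'
#' @param tab A [manhattan_table()] result (one region, or faceted by
#'   consecutive calls).
#' @param region Region to plot (default: first in the table).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `tab`.
#' @export
plot_manhattan <- function(tab, region = NULL, ...) {
  if (is.null(region)) region <- tab$region_id[1L]
  d <- tab[tab$region_id == region, , drop = FALSE]
  chrom_idx <- as.integer(factor(d$chrom, levels = unique(d$chrom)))
  graphics::plot(seq_len(nrow(d)), d$signed_score, pch = 16, cex = 0.5,
                 col = ifelse(chrom_idx %% 2L == 0L, "grey55", "grey15"),
                 xlab = "genes (chromosomal order)",
                 ylab = "signed Significance Score", main = region, ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(tab)
}
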