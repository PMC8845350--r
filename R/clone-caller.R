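#' Group cells into clones from sgRNA overlap
#'
#' Agglomerative clone calling over detected guide sets. Cells are visited in
#' a fixed, documented order; each cell is tested for significant sgRNA
#' overlap (hypergeometric, Bonferroni-corrected at `alpha`) against every
#' clone already in the dictionary. A cell significant with no clone founds a
#' new clone; with exactly one clone it joins that clone; with more than one
#' distinct clone it is flagged as a likely cell doublet and excluded from all
#' clones. Non-clonal cells thus end up as singleton clones, and an empty
#' guide set always founds a singleton, never a doublet.
#'
#' The default visiting order is *ascending* total guide UMI (ties broken by
#' barcode): multiplet-like barcodes carry the most guide material, and
#' deferring them guarantees that the clones they might span already exist in
#' the dictionary, which is what makes inline doublet flagging effective.
#'
#' The Bonferroni denominator in the default `"tests"` mode is the number of
#' hypothesis tests actually performed in a pass (the number of clones in the
#' dictionary summed over cells as each is visited). Because that count
#' depends on the threshold it defines, it is solved as a fixed point: the
#' first pass uses `n_cells` as denominator, each subsequent pass reuses the
#' previous pass's test count, stopping when the assignment no longer changes
#' (at most `max_passes`). `"fixed"` mode instead uses
#' `n_cells x final clone count`.
#'
#' @param sets A [guide_sets] object for all cells of one experiment.
#' @param alpha Family-wise significance level for the corrected test
#'   (default 0.05).
#' @param order Cell visiting order: `"umi_asc"` (default), `"umi_desc"`,
#'   `"lex"` (barcode), or `"given"` (input order).
#' @param compare Comparison target representing a clone: its `"founder"`
#'   cell (default; dictionary semantics, O(cells x clones)) or `"members"`
#'   (strict mode: significant if significant against any member).
#' @param bonferroni Denominator mode, `"tests"` (default) or `"fixed"`.
#' @param max_passes Cap on fixed-point passes (default 4).
#' @return A `clone_assignment`: `data.frame` with columns `cell_id`, `clone`
#'   (integer label, `NA` for doublets), `is_doublet`, `n_guides`,
#'   `best_log10p` (smallest overlap p-value against any clone tested);
#'   attributes `founders` (founder cell id per clone), `members` (list of
#'   member cell ids), `denominator`, `n_tests`, `alpha`, `order`, `passes`.
#' @export
group_clones <- function(sets, alpha = 0.05,
                         order = c("umi_asc", "umi_desc", "lex", "given"),
                         compare = c("founder", "members"),
                         bonferroni = c("tests", "fixed"),
                         max_passes = 4L) {
  stopifnot(inherits(sets, "guide_sets"))
  order <- match.arg(order)
  compare <- match.arg(compare)
  bonferroni <- match.arg(bonferroni)
  n_cells <- length(sets$cell_id)
  if (n_cells == 0L) stop("no cells to group")
  tot <- vapply(sets$umis, function(u) sum(as.numeric(u)), 0)
  ord <- switch(order,
    umi_asc = order(tot, sets$cell_id),
    umi_desc = order(-tot, sets$cell_id),
    lex = order(sets$cell_id),
    given = seq_len(n_cells)
  )
  denom <- n_cells
  prev <- NULL
  passes <- 0L
  repeat {
    passes <- passes + 1L
    res <- .clone_pass(sets, ord, alpha, denom, compare)
    if ((!is.null(prev) && identical(prev$clone, res$clone) &&
         identical(prev$doublet, res$doublet)) || passes >= max_passes) break
    denom <- if (bonferroni == "tests") max(res$n_tests, 1) else
      as.numeric(n_cells) * max(res$n_clones, 1L)
    prev <- res
  }
  out <- data.frame(
    cell_id = sets$cell_id,
    clone = res$clone,
    is_doublet = res$doublet,
    n_guides = lengths(sets$guides),
    best_log10p = res$best,
    stringsAsFactors = FALSE
  )
  members <- split(sets$cell_id[!res$doublet], res$clone[!res$doublet])
  members <- members[as.character(seq_len(res$n_clones))]
  structure(out,
            founders = sets$cell_id[res$founder_of],
            members = unname(members),
            denominator = denom, n_tests = res$n_tests,
            alpha = alpha, order = order, compare = compare,
            bonferroni = bonferroni, passes = passes,
            class = c("clone_assignment", "data.frame"))
}

# one full grouping pass at a fixed Bonferroni denominator
.clone_pass <- function(sets, ord, alpha, denom, compare) {
  M <- length(sets$guide_ids)
  n_cells <- length(sets$cell_id)
  log_thresh <- log10(alpha) - log10(denom)
  clone <- rep(NA_integer_, n_cells)
  doublet <- logical(n_cells)
  best <- rep(NA_real_, n_cells)
  founder_of <- integer(n_cells)      # cell index founding each clone
  founder_n <- integer(n_cells)      # founder guide count per clone
  n_clones <- 0L
  inc <- vector("list", M)           # guide index -> clone ids carrying it
  inc_cell <- vector("list", M)      # strict mode: guide -> member cell idx
  member_clone <- integer(n_cells)   # strict mode: cell idx -> clone
  n_tests <- 0
  for (i in ord) {
    g <- sets$guides[[i]]
    n <- length(g)
    n_tests <- n_tests + n_clones
    sig <- integer(0)
    if (n > 0L && n_clones > 0L) {
      if (compare == "founder") {
        hits <- unlist(inc[g], use.names = FALSE)
        if (length(hits)) {
          tab <- tabulate(hits, nbins = n_clones)
          cand <- which(tab > 0L)
          lp <- .overlap_log10p(tab[cand], M, n, founder_n[cand])
          best[i] <- min(lp)
          sig <- cand[lp < log_thresh]
        }
      } else {
        hits <- unlist(inc_cell[g], use.names = FALSE)
        if (length(hits)) {
          tab <- tabulate(hits, nbins = n_cells)
          cand_cells <- which(tab > 0L)
          lp <- .overlap_log10p(tab[cand_cells], M, n,
                                lengths(sets$guides)[cand_cells])
          best[i] <- min(lp)
          sig <- unique(member_clone[cand_cells[lp < log_thresh]])
        }
      }
    }
    if (length(sig) == 0L) {
      n_clones <- n_clones + 1L
      founder_of[n_clones] <- i
      founder_n[n_clones] <- n
      clone[i] <- n_clones
      for (gg in g) inc[[gg]] <- c(inc[[gg]], n_clones)
      if (compare == "members") {
        member_clone[i] <- n_clones
        for (gg in g) inc_cell[[gg]] <- c(inc_cell[[gg]], i)
      }
    } else if (length(sig) == 1L) {
      clone[i] <- sig
      if (compare == "members") {
        member_clone[i] <- sig
        for (gg in g) inc_cell[[gg]] <- c(inc_cell[[gg]], i)
      }
    } else {
      doublet[i] <- TRUE
    }
  }
  list(clone = clone, doublet = doublet, best = best,
       founder_of = founder_of[seq_len(n_clones)], n_clones = n_clones,
       n_tests = n_tests)
}

#' @export
print.clone_assignment <- function(x, ...) {
  sz <- table(x$clone)
  cat(sprintf(paste0(
    "clone_assignment: %d cells -> %d clones (%d of size >= 2), %d doublets\n",
    "  Bonferroni denominator %s (alpha = %g, order = %s, %d pass(es))\n"),
    nrow(x), length(sz), sum(sz >= 2), sum(x$is_doublet),
    format(attr(x, "denominator"), big.mark = ","), attr(x, "alpha"),
    attr(x, "order"), attr(x, "passes")))
  invisible(x)
}

#' Summarize a clone assignment
#'
#' Per-clone sizes, the major-clone flag (more than `major_size` cells), the
#' clonal/non-clonal split (clonal = clone of size >= 2) and the mean pairwise
#' sgRNA overlap rate inside each multi-cell clone. For large clones the
#' pairwise rate is estimated from a seeded subsample of pairs.
#'
#' @param assignment A `clone_assignment` from [group_clones()].
#' @param sets The [guide_sets] the assignment was computed from.
#' @param major_size Major-clone threshold: a clone is major when its size is
#'   strictly greater than this (default 100).
#' @param max_pairs Maximum pairs sampled per clone for the overlap rate.
#' @param seed Seed for the pair subsampling (local RNG, does not disturb the
#'   session RNG state).
#' @return `clone_table`: `data.frame` with columns `clone`, `size`,
#'   `founder`, `mean_overlap_rate`, `is_clonal`, `is_major`; attributes
#'   `clonal_fraction` (fraction of non-doublet cells in clones of size >= 2),
#'   `n_doublets`, `n_cells`, `n_major`.
#' @export
summarize_clones <- function(assignment, sets, major_size = 100,
                             max_pairs = 200, seed = 1) {
  stopifnot(inherits(assignment, "clone_assignment"),
            inherits(sets, "guide_sets"))
  members <- attr(assignment, "members")
  founders <- attr(assignment, "founders")
  gidx <- stats::setNames(sets$guides, sets$cell_id)
  rate <- vapply(members, function(cells) {
    if (length(cells) < 2L) return(NA_real_)
    pairs <- utils::combn(length(cells), 2L)
    if (ncol(pairs) > max_pairs) {
      pairs <- pairs[, .with_local_seed(seed, sample.int(ncol(pairs), max_pairs)),
                     drop = FALSE]
    }
    g <- gidx[cells]
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      overlap_rate(g[[pairs[1L, p]]], g[[pairs[2L, p]]])
    }, 0))
  }, 0)
  size <- lengths(members)
  tab <- data.frame(
    clone = seq_along(members),
    size = as.integer(size),
    founder = founders,
    mean_overlap_rate = rate,
    is_clonal = size >= 2L,
    is_major = size > major_size,
    stringsAsFactors = FALSE
  )
  n_doublets <- sum(assignment$is_doublet)
  structure(tab,
            clonal_fraction = sum(size[size >= 2L]) / max(sum(size), 1L),
            n_doublets = n_doublets,
            n_cells = nrow(assignment),
            n_major = sum(tab$is_major),
            major_size = major_size,
            class = c("clone_table", "data.frame"))
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf(paste0(
    "clone_table: %d clones over %d cells (%d doublets)\n",
    "  clonal fraction %.1f%%, %d major clone(s) (> %s cells)\n"),
    nrow(x), attr(x, "n_cells"), attr(x, "n_doublets"),
    100 * attr(x, "clonal_fraction"), attr(x, "n_major"),
    format(attr(x, "major_size"))))
  invisible(x)
}

#' Flag high-confidence non-clonal cells
#'
#' A singleton cell is called high-confidence non-clonal when its best
#' (smallest) overlap p-value against *every other cell* fails even an
#' uncorrected threshold — a stricter condition than merely failing the
#' Bonferroni-corrected clone test.
#'
#' @param assignment A `clone_assignment`.
#' @param sets The matching [guide_sets].
#' @param alpha Uncorrected threshold (default 0.05).
#' @return Logical vector along `assignment$cell_id`.
#' @export
classify_nonclonal <- function(assignment, sets, alpha = 0.05) {
  stopifnot(inherits(assignment, "clone_assignment"))
  M <- length(sets$guide_ids)
  sizes <- lengths(attr(assignment, "members"))
  singleton <- !assignment$is_doublet & sizes[assignment$clone] == 1L
  ns <- lengths(sets$guides)
  # incidence guide -> cells, to scan each singleton against all cells
  inc <- vector("list", M)
  for (i in seq_along(sets$guides)) {
    for (gg in sets$guides[[i]]) inc[[gg]] <- c(inc[[gg]], i)
  }
  out <- logical(nrow(assignment))
  thresh <- log10(alpha)
  for (i in which(singleton)) {
    hits <- unlist(inc[sets$guides[[i]]], use.names = FALSE)
    hits <- hits[hits != i]
    if (!length(hits)) { out[i] <- TRUE; next }
    tab <- tabulate(hits, nbins = length(ns))
    cand <- which(tab > 0L)
    lp <- .overlap_log10p(tab[cand], M, ns[i], ns[cand])
    out[i] <- min(lp) >= thresh
  }
  out
}

# evaluate expr with a temporary RNG state seeded at `seed`
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
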