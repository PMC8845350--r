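#' Log10 p-value of sgRNA overlap between two cells
#'
#' Tests whether two cells share more sgRNAs than expected by chance under a
#' hypergeometric null: cell 1 carries `n` of the `M` library guides, cell 2
#' draws `N` guides, and `X` is the number shared. The reported value is
#' `log10 P(X >= overlap)`, the survival probability at the observed overlap.
#' All arithmetic stays in log space (via [stats::phyper()] with
#' `log.p = TRUE`), so p-values far below double underflow (e.g. 1e-300 and
#' smaller) remain representable and comparable.
#'
#' @param overlap Integer vector, observed number of shared guides.
#' @param M Integer, sgRNA library size.
#' @param n Integer vector, number of guides detected in cell 1.
#' @param N Integer vector, number of guides detected in cell 2.
#' @return Numeric vector of `log10 P(X >= overlap)`; always `<= 0`, with 0
#'   meaning the overlap (or a larger one) is certain or unsurprising
#'   (`p = 1`).
#' @examples
#' overlap_log10_pvalue(0, 20000, 30, 30)   # 0: zero overlap is the sure event
#' overlap_log10_pvalue(22, 20000, 30, 30)  # astronomically small
#' @export
overlap_log10_pvalue <- function(overlap, M, n, N) {
  if (any(M < 1)) stop("library size M must be >= 1")
  if (any(n < 0) || any(N < 0) || any(overlap < 0)) {
    stop("overlap, n and N must be non-negative")
  }
  if (any(n > M) || any(N > M)) {
    stop("guide counts n and N cannot exceed the library size M")
  }
  if (any(overlap > pmin(n, N))) {
    stop("overlap cannot exceed min(n, N)")
  }
  .overlap_log10p(overlap, M, n, N)
}

# fast path without validation, used inside the grouping loop
.overlap_log10p <- function(overlap, M, n, N) {
  stats::phyper(overlap - 1, n, M - n, N,
                lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Jaccard overlap rate of two guide sets
#'
#' The sgRNA overlap rate between two cells: the number of shared guides
#' (intersection) divided by the number of distinct guides carried by either
#' cell (union). Symmetric; 1 for identical sets, 0 for disjoint sets.
#'
#' @param a,b Character (or integer) vectors of guide identifiers.
#' @return Fraction in `[0, 1]`, or `NA` when both sets are empty (the rate is
#'   undefined and reported as such).
#' @export
overlap_rate <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(a) + length(b) - sum(a %in% b)
  if (u == 0L) {
    warning("overlap rate of two empty guide sets is undefined")
    return(NA_real_)
  }
  sum(a %in% b) / u
}

#' Pairwise sgRNA-overlap p-value matrix
#'
#' Computes the log10 hypergeometric overlap p-value for every pair among a
#' sample of cells, e.g. to draw the clonal block-structure heatmap. The
#' diagonal holds each cell's self-overlap p-value (its full set against
#' itself), the natural lower bound for that cell's pairings.
#'
#' @param sets A [guide_sets] object.
#' @param cells Optional character vector of cell ids to restrict to (order is
#'   preserved in the output); default all cells.
#' @return Symmetric numeric matrix of log10 p-values with cell ids as
#'   dimnames.
#' @export
pairwise_pvalue_matrix <- function(sets, cells = NULL) {
  stopifnot(inherits(sets, "guide_sets"))
  idx <- if (is.null(cells)) seq_along(sets$cell_id) else {
    m <- match(cells, sets$cell_id)
    if (anyNA(m)) stop("unknown cell ids: ", paste(cells[is.na(m)], collapse = ", "))
    m
  }
  M <- length(sets$guide_ids)
  g <- sets$guides[idx]
  ns <- lengths(g)
  k <- length(idx)
  out <- matrix(0, k, k, dimnames = list(sets$cell_id[idx], sets$cell_id[idx]))
  for (i in seq_len(k)) {
    ov <- vapply(seq_len(i), function(j) sum(g[[i]] %in% g[[j]]), 0L)
    lp <- .overlap_log10p(ov, M, ns[i], ns[seq_len(i)])
    out[i, seq_len(i)] <- lp
    out[seq_len(i), i] <- lp
  }
  out
}
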