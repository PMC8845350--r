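# Independent oracles and fixture builders shared across the suite.

# Exhaustive enumeration oracle for the sgRNA-overlap survival probability:
# over all C(M, N) equally likely draws of N guides from a library of M in
# which cell 1 carries guides 1..n, the fraction whose overlap with 1..n is
# at least `overlap`. Feasible for M <= ~15.
enum_overlap_sf <- function(overlap, M, n, N) {
  draws <- utils::combn(M, N)
  ov <- colSums(draws <= n)
  mean(ov >= overlap)
}

# Brute-force knee scan: distances of every cumulative point to the chord,
# computed point by point (independent of the vectorized implementation).
brute_knee <- function(umis_sorted_desc) {
  u <- umis_sorted_desc
  G <- length(u)
  y <- cumsum(u) / sum(u)
  d <- vapply(seq_len(G), function(i) y[i] - i / G, 0)
  which.max(d)
}

# Small deterministic guide_sets fixture from explicit id sets.
sets_from_list <- function(guides_by_cell, guide_ids, umi = 10) {
  guide_sets(
    cell_id = names(guides_by_cell),
    guide_ids = guide_ids,
    guides = lapply(guides_by_cell, function(g) match(g, guide_ids)),
    umis = lapply(guides_by_cell, function(g) rep(umi, length(g)))
  )
}

# Write a CellRanger-style MTX trio into a temp dir; returns the paths.
write_mtx_fixture <- function(counts, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  clonescreen::write_guide_matrix(counts, dir)
}

# A small dense matrix with dimnames for io tests.
toy_counts <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3), j = c(1, 3, 2, 1, 4), x = c(5, 2, 7, 1, 9),
    dims = c(3, 4),
    dimnames = list(paste0("cell", 1:3), paste0("sg", 1:4)))
  methods::as(m, "CsparseMatrix")
}
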