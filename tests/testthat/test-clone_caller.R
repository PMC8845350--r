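test_that("the overlap test matches exhaustive enumeration on a small library", {
  # M = 10 guides, cell 1 carries 4, cell 2 draws 5, overlap >= 3:
  # enumerating all C(10, 5) = 252 draws gives 66 qualifying ones.
  p_enum <- enum_overlap_sf(3, 10, 4, 5)
  expect_equal(p_enum, 66 / 252)
  expect_equal(10^overlap_log10_pvalue(3, 10, 4, 5), p_enum,
               tolerance = 1e-12)
})

test_that("sure events give log10 p = 0 and domain violations error", {
  expect_equal(overlap_log10_pvalue(0, 20000, 30, 30), 0)
  # cell 1 carries the whole library: any draw overlaps fully
  expect_equal(overlap_log10_pvalue(5, 12, 12, 5), 0)
  expect_error(overlap_log10_pvalue(6, 12, 4, 5), "min")
  expect_error(overlap_log10_pvalue(3, 10, 11, 5), "library size")
})

test_that("the overlap p-value is monotone non-increasing in the overlap", {
  for (spec in list(c(M = 100, n = 20, N = 30), c(M = 20139, n = 30, N = 30))) {
    lp <- overlap_log10_pvalue(0:min(spec["n"], spec["N"]), spec["M"],
                               spec["n"], spec["N"])
    expect_true(all(diff(lp) <= 1e-12))
  }
})

test_that("deep-tail p-values stay representable in log space", {
  lp <- overlap_log10_pvalue(30, 20139, 30, 30)
  expect_lt(lp, -90)
  expect_true(is.finite(lp))
})

test_that("overlap rates follow the intersection-over-union definition", {
  expect_equal(overlap_rate(letters[1:5], letters[1:5]), 1)
  expect_equal(overlap_rate(letters[1:3], letters[4:6]), 0)
  expect_equal(overlap_rate(c("a", "b", "c"), c("b", "c", "d")), 2 / 4)
  expect_warning(r <- overlap_rate(character(0), character(0)), "undefined")
  expect_true(is.na(r))
})

test_that("identical cells form one clone; disjoint cells stay apart", {
  lib <- sprintf("g%05d", 1:20000)
  shared <- lib[1:30]
  sets <- sets_from_list(list(c1 = shared, c2 = shared), lib)
  asg <- group_clones(sets)
  expect_equal(asg$clone[1L], asg$clone[2L])
  expect_false(any(asg$is_doublet))

  sets3 <- sets_from_list(
    list(c1 = lib[1:30], c2 = lib[31:60], c3 = lib[61:90]), lib)
  asg3 <- group_clones(sets3)
  expect_equal(length(unique(asg3$clone)), 3L)
})

test_that("a cell spanning two established clones is flagged as a doublet", {
  lib <- sprintf("g%05d", 1:20000)
  a <- lib[1:30]
  b <- lib[101:130]
  cells <- list(a1 = a, a2 = a, b1 = b, b2 = b, dbl = c(a, b))
  sets <- sets_from_list(cells, lib)
  asg <- group_clones(sets)  # ascending UMI puts the 60-guide cell last
  expect_true(asg$is_doublet[asg$cell_id == "dbl"])
  expect_false(any(asg$is_doublet[asg$cell_id != "dbl"]))
  expect_equal(asg$clone[asg$cell_id == "a1"], asg$clone[asg$cell_id == "a2"])
  expect_equal(asg$clone[asg$cell_id == "b1"], asg$clone[asg$cell_id == "b2"])
})

test_that("an empty guide set founds a singleton clone, never a doublet", {
  lib <- sprintf("g%05d", 1:1000)
  sets <- sets_from_list(list(c1 = lib[1:10], c2 = lib[1:10],
                              empty = character(0)), lib)
  asg <- group_clones(sets)
  expect_false(asg$is_doublet[asg$cell_id == "empty"])
  expect_equal(sum(asg$clone == asg$clone[asg$cell_id == "empty"]), 1L)
})

test_that("grouping is invariant to relabeling of guide identifiers", {
  cfg <- sim_config(M = 2000, guides_per_cell = 15, n_clonal = 60,
                    n_nonclonal = 40, n_clones = 3, ambient_guides = 0,
                    seed = 11)
  sim <- simulate_population(cfg)
  sets <- detect_guides(sim$counts)
  perm <- sample(ncol(sim$counts))
  m2 <- sim$counts[, perm, drop = FALSE]
  colnames(m2) <- sprintf("relabeled_%05d", seq_len(ncol(m2)))
  sets2 <- detect_guides(m2)
  a1 <- group_clones(sets)
  a2 <- group_clones(sets2)
  expect_equal(a1$clone, a2$clone)
  expect_equal(a1$is_doublet, a2$is_doublet)
})

test_that("clone sizes plus doublets always partition the input cells", {
  cfg <- sim_config(M = 20139, n_clonal = 150, n_nonclonal = 150,
                    n_clones = 3, seed = 5)
  sim <- simulate_population(cfg)
  dbl <- simulate_doublets(sim$counts, sim$truth, fraction = 0.04,
                           pairing = "distinct_clones", seed = 6)
  sets <- detect_guides(dbl$counts)
  asg <- group_clones(sets)
  sizes <- lengths(attr(asg, "members"))
  expect_equal(sum(sizes) + sum(asg$is_doublet), nrow(asg))
  expect_true(all(!is.na(asg$clone) | asg$is_doublet))
  # every founder is a member of its own clone
  members <- attr(asg, "members")
  founders <- attr(asg, "founders")
  expect_true(all(mapply(function(f, m) f %in% m, founders, members)))
})

test_that("founder and all-members comparison agree on well-separated clones", {
  cfg <- sim_config(M = 5000, guides_per_cell = 20, n_clonal = 40,
                    n_nonclonal = 20, n_clones = 2, seed = 9)
  sim <- simulate_population(cfg)
  sets <- detect_guides(sim$counts)
  a_founder <- group_clones(sets, compare = "founder")
  a_members <- group_clones(sets, compare = "members")
  expect_equal(mclust::adjustedRandIndex(a_founder$clone, a_members$clone), 1)
})

test_that("clone summaries count sizes, major clones and the clonal fraction", {
  lib <- sprintf("g%05d", 1:20000)
  a <- lib[1:30]
  sets <- sets_from_list(
    list(a1 = a, a2 = a, a3 = a, s1 = lib[201:230], s2 = lib[401:430]), lib)
  asg <- group_clones(sets)
  tab <- summarize_clones(asg, sets)
  expect_equal(sort(tab$size, decreasing = TRUE), c(3L, 1L, 1L))
  expect_equal(attr(tab, "clonal_fraction"), 0.6)
  expect_equal(attr(tab, "n_major"), 0L)
  expect_equal(tab$mean_overlap_rate[tab$size == 3L], 1)
  # the major flag requires strictly more than `major_size` cells
  many <- stats::setNames(rep(list(a), 101), paste0("m", 1:101))
  asg2 <- group_clones(sets_from_list(many, lib))
  tab2 <- summarize_clones(asg2, sets_from_list(many, lib))
  expect_equal(attr(tab2, "n_major"), 1L)
  tab3 <- summarize_clones(asg2, sets_from_list(many, lib), major_size = 101)
  expect_equal(attr(tab3, "n_major"), 0L)
})

test_that("pairwise p-value matrices are symmetric with block structure by clone", {
  cfg <- sim_config(M = 20139, n_clonal = 60, n_nonclonal = 40, n_clones = 2,
                    seed = 13)
  sim <- simulate_population(cfg)
  sets <- detect_guides(sim$counts)
  pm <- pairwise_pvalue_matrix(sets)
  expect_true(isSymmetric(pm))
  expect_true(all(pm <= 0))
  same <- outer(sim$truth$clone, sim$truth$clone, function(a, b)
    !is.na(a) & !is.na(b) & a == b)
  diag(same) <- NA
  off_diag <- !is.na(same)
  expect_lt(max(pm[off_diag & same]), -20)        # within-clone: tiny p
  expect_gt(min(pm[off_diag & !same]), -8)        # across: unremarkable
  # two identical cells: off-diagonal equals the self-overlap diagonal
  lib <- sprintf("g%05d", 1:20000)
  twin <- sets_from_list(list(t1 = lib[1:30], t2 = lib[1:30]), lib)
  pm2 <- pairwise_pvalue_matrix(twin)
  expect_equal(pm2[1L, 2L], pm2[1L, 1L])
  # disjoint cells: off-diagonal log10 p = 0
  dis <- sets_from_list(list(d1 = lib[1:30], d2 = lib[31:60]), lib)
  expect_equal(pairwise_pvalue_matrix(dis)[1L, 2L], 0)
})

test_that("high-confidence non-clonal calls are stricter than mere singletons", {
  lib <- sprintf("g%05d", 1:2000)
  a <- lib[1:20]
  sets <- sets_from_list(
    list(a1 = a, a2 = a,
         near = c(a[1:4], lib[501:516]),   # some uncorrected-significant overlap
         far = lib[1001:1020]), lib)
  asg <- group_clones(sets)
  hc <- classify_nonclonal(asg, sets)
  expect_false(hc[asg$cell_id == "a1"])
  expect_true(hc[asg$cell_id == "far"])
  expect_false(hc[asg$cell_id == "near"])
})
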