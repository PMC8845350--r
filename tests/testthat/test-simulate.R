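test_that("full sharing makes clone members carry identical guide sets", {
  cfg <- sim_config(M = 2000, guides_per_cell = 20, clone_share = 1,
                    n_clonal = 10, n_nonclonal = 0, n_clones = 1,
                    umi_mean = 60, umi_dispersion = 0.01,
                    ambient_guides = 0, seed = 2)
  sim <- simulate_population(cfg)
  sets <- apply(sim$counts > 0, 1L, which, simplify = FALSE)
  expect_true(all(vapply(sets, identical, TRUE, sets[[1L]])))
})

test_that("a fixed seed reproduces the population byte-for-byte", {
  cfg <- sim_config(M = 3000, n_clonal = 50, n_nonclonal = 50, n_clones = 2,
                    seed = 17)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth$clone, b$truth$clone)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_guide_matrix(a$counts, d1)
  write_guide_matrix(b$counts, d2)
  expect_identical(readLines(file.path(d1, "matrix.mtx")),
                   readLines(file.path(d2, "matrix.mtx")))
})

test_that("clonal cells share round(r*k) founder guides plus random fill", {
  cfg <- sim_config(M = 20139, guides_per_cell = 30, clone_share = 0.75,
                    n_clonal = 100, n_nonclonal = 0, n_clones = 2,
                    ambient_guides = 0, seed = 23)
  sim <- simulate_population(cfg)
  founders <- attr(sim$truth, "founder_sets")
  true_sets <- attr(sim$truth, "true_guides")
  # round-half-to-even: 0.75 * 30 = 22.5 -> 22 founder guides per member
  for (i in seq_len(20)) {
    cl <- as.integer(sub("clone_", "", sim$truth$clone[i]))
    planted <- attr(sim$truth, "config")$guides_per_cell  # 30 drawn guides
    drawn_from_founder <- sum(true_sets[[i]] %in% founders[[cl]])
    # UMI dropout can only remove guides, never add
    expect_lte(length(true_sets[[i]]), planted)
    expect_gte(drawn_from_founder / length(true_sets[[i]]), 0.6)
  }
  # the intended overlap before dropout is exactly round(0.75 * 30) = 22
  expect_identical(round(0.75 * 30), 22)
})

test_that("per-cell detection retains at least 90% of planted guides at default depth", {
  cfg <- sim_config(n_clonal = 100, n_nonclonal = 100, n_clones = 2, seed = 31)
  sim <- simulate_population(cfg)
  sets <- detect_guides(sim$counts)
  true_sets <- attr(sim$truth, "true_guides")
  k <- cfg$guides_per_cell
  retained <- vapply(seq_along(sets$guides), function(i)
    sum(sets$guides[[i]] %in% true_sets[[i]]), 0L)
  expect_gte(mean(retained), 0.9 * k)
  expect_lte(mean(retained), k)
  # detected sets are dominated by true guides, not ambient noise
  expect_gte(mean(retained / lengths(sets$guides)), 0.95)
})

test_that("doublet merging unions guide sets and sums UMIs", {
  cfg <- sim_config(M = 2000, guides_per_cell = 10, n_clonal = 20,
                    n_nonclonal = 0, n_clones = 2, ambient_guides = 0,
                    seed = 3)
  sim <- simulate_population(cfg)
  same <- simulate_doublets(sim$counts, sim$truth, fraction = 0)
  expect_identical(same$counts, sim$counts)
  dbl <- simulate_doublets(sim$counts, sim$truth, fraction = 0.1,
                           pairing = "distinct_clones", seed = 4)
  expect_equal(sum(dbl$truth$is_doublet), 2L)
  expect_equal(sum(dbl$counts), sum(sim$counts))  # UMIs conserved
  expect_equal(nrow(dbl$counts), nrow(sim$counts) - 2L)
})

test_that("a same-clone merge is absorbed into its clone, a cross-clone merge is flagged", {
  cfg <- sim_config(M = 20139, guides_per_cell = 30, n_clonal = 60,
                    n_nonclonal = 0, n_clones = 2, seed = 41)
  sim <- simulate_population(cfg)
  cl1 <- which(sim$truth$clone == "clone_01")
  cl2 <- which(sim$truth$clone == "clone_02")
  same_merge <- sim$counts[cl1[1L], ] + sim$counts[cl1[2L], ]
  cross_merge <- sim$counts[cl1[3L], ] + sim$counts[cl2[1L], ]
  counts <- rbind(sim$counts[-c(cl1[1:3], cl2[1L]), , drop = FALSE],
                  Matrix::Matrix(rbind(same_merge = same_merge,
                                       cross_merge = cross_merge),
                                 sparse = TRUE))
  sets <- detect_guides(counts)
  asg <- group_clones(sets)
  expect_false(asg$is_doublet[asg$cell_id == "same_merge"])
  expect_true(asg$is_doublet[asg$cell_id == "cross_merge"])
  # the same-clone merge joins its clone's other members
  mate <- asg$clone[asg$cell_id == sim$truth$cell_id[cl1[4L]]]
  expect_equal(asg$clone[asg$cell_id == "same_merge"], mate)
})

test_that("recovery metrics behave at their limits", {
  truth <- structure(
    data.frame(cell_id = paste0("c", 1:6),
               clone = c("A", "A", "A", NA, NA, NA),
               is_doublet = FALSE, stringsAsFactors = FALSE),
    class = c("sim_truth", "data.frame"))
  perfect <- structure(
    data.frame(cell_id = paste0("c", 1:6),
               clone = c(1L, 1L, 1L, 2L, 3L, 4L),
               is_doublet = FALSE, stringsAsFactors = FALSE),
    founders = paste0("c", c(1, 4, 5, 6)),
    members = list(paste0("c", 1:3), "c4", "c5", "c6"),
    class = c("clone_assignment", "data.frame"))
  ev <- evaluate_recovery(truth, perfect)
  expect_equal(ev$ari, 1)
  expect_equal(ev$pair_precision, 1)
  expect_equal(ev$pair_recall, 1)
  shattered <- perfect
  shattered$clone <- 1:6
  attr(shattered, "members") <- as.list(paste0("c", 1:6))
  ev2 <- evaluate_recovery(truth, shattered)
  expect_equal(ev2$pair_recall, 0)
  expect_true(is.na(ev2$pair_precision))  # no predicted pairs
})

test_that("random labels score an adjusted Rand index near zero", {
  set.seed(19)
  n <- 200
  truth <- structure(
    data.frame(cell_id = paste0("c", 1:n),
               clone = sample(paste0("t", 1:10), n, TRUE),
               is_doublet = FALSE, stringsAsFactors = FALSE),
    class = c("sim_truth", "data.frame"))
  aris <- replicate(20, {
    lab <- sample(1:10, n, TRUE)
    asg <- structure(
      data.frame(cell_id = paste0("c", 1:n), clone = lab,
                 is_doublet = FALSE, stringsAsFactors = FALSE),
      members = split(paste0("c", 1:n), lab),
      class = c("clone_assignment", "data.frame"))
    evaluate_recovery(truth, asg)$ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("without clonal sharing, significant pair overlap is controlled at alpha", {
  # null populations: every cell an independent random guide set
  frac_sig <- vapply(1:10, function(s) {
    cfg <- sim_config(M = 20139, guides_per_cell = 30, n_clonal = 0,
                      n_nonclonal = 60, ambient_guides = 0, seed = 100 + s)
    sim <- simulate_population(cfg)
    sets <- detect_guides(sim$counts)
    pm <- pairwise_pvalue_matrix(sets)
    off <- pm[upper.tri(pm)]
    n_tests <- length(off)
    mean(off < log10(0.05 / n_tests))
  }, 0)
  expect_lte(mean(frac_sig), 0.05)
})

test_that("planted expression segments shift counts only where specified", {
  ann <- simulate_gene_annotation(600, paste0("chr", 1:6))
  labs <- stats::setNames(c(rep("A", 40), rep("B", 40), rep(NA, 40)),
                          sprintf("c%03d", 1:120))
  spec <- data.frame(clone = c("A", "B"), chrom = c("chr2", "chr5"),
                     start = c(0, 0), end = c(100 * 1e5, 100 * 1e5),
                     fold_change = c(0.5, 1.5))
  expr <- simulate_expression_with_cnv(labs, ann, spec, seed = 8)
  aff <- ann$gene_id[ann$chrom == "chr2"]
  unaff <- ann$gene_id[ann$chrom %in% c("chr1", "chr3")]
  a_cells <- names(labs)[!is.na(labs) & labs == "A"]
  bg_cells <- names(labs)[is.na(labs)]
  # clone A's chr2 counts drop by about half relative to unassigned cells;
  # off-segment chromosomes are unaffected
  expect_lt(sum(expr[a_cells, aff]) / sum(expr[bg_cells, aff]), 0.65)
  expect_equal(sum(expr[a_cells, unaff]) / sum(expr[bg_cells, unaff]), 1,
               tolerance = 0.05)
  expect_error(
    simulate_expression_with_cnv(labs, ann,
      data.frame(clone = "A", chrom = "chrZ", start = 0, end = 1,
                 fold_change = 2), seed = 1),
    "unannotated")
})
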