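#' Simulation configuration for a guide-barcoded cell population
#'
#' Defines the study conditions of the clone simulation: a library of `M`
#' sgRNAs, clonal cells carrying `guides_per_cell` guides of which a fraction
#' `clone_share` is drawn from their clone's founder set and the remainder
#' uniformly from the full library, and non-clonal cells carrying purely
#' random sets. Guide UMI counts are negative binomial around `umi_mean`;
#' each cell additionally receives low-level ambient guide molecules (1-2
#' UMIs on random guides), the background the saturation-knee filter is built
#' to remove.
#'
#' @param M sgRNA library size (default 20139).
#' @param guides_per_cell True guides per cell `k` (default 30).
#' @param clone_share Fraction `r` of a clonal cell's guides drawn from its
#'   clone founder set (default 0.75). The shared count is `round(r * k)`
#'   with round-half-to-even.
#' @param n_clonal,n_nonclonal Numbers of clonal and non-clonal cells
#'   (defaults 1000 and 1000).
#' @param n_clones Number of planted clones splitting the clonal cells as
#'   evenly as possible (default 10).
#' @param umi_mean Mean UMI per true guide (default 15).
#' @param umi_dispersion Negative-binomial dispersion `a` (variance
#'   `mu + a mu^2`; default 0.1).
#' @param ambient_guides Expected number of ambient guide species per cell
#'   (Poisson; default 100). Set 0 for noise-free sets.
#' @param seed Random seed; a fixed seed makes the output bit-identical.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(M = 20139, guides_per_cell = 30, clone_share = 0.75,
                       n_clonal = 1000, n_nonclonal = 1000, n_clones = 10,
                       umi_mean = 15, umi_dispersion = 0.1,
                       ambient_guides = 100, seed = 1) {
  if (clone_share < 0 || clone_share > 1) stop("clone_share must be in [0, 1]")
  if (guides_per_cell > M) stop("guides_per_cell cannot exceed the library size")
  if (n_clonal > 0 && n_clones < 1) stop("need at least one clone for clonal cells")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a guide matrix with planted clonal structure
#'
#' Each planted clone has a founder guide set of size `k`; every member
#' carries `round(r * k)` guides subsampled from it plus `k - round(r * k)`
#' guides drawn from the rest of the library. Non-clonal cells carry `k`
#' uniform guides. True-guide UMIs are negative binomial
#' (`mu = umi_mean`, dispersion `umi_dispersion`); ambient guide species
#' (Poisson(`ambient_guides`) per cell) receive 1-2 UMIs. Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (sparse cells x guides UMI matrix) and `truth`
#'   (`data.frame` of class `sim_truth`: `cell_id`, `clone` (`NA` for
#'   non-clonal cells), `is_doublet`; attribute `founder_sets` and
#'   `true_guides`, lists of guide indices).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c0 <- config
  .with_local_seed(c0$seed, {
    M <- c0$M; k <- c0$guides_per_cell
    n_shared <- round(c0$clone_share * k)
    clone_of <- if (c0$n_clonal > 0)
      rep(seq_len(c0$n_clones), length.out = c0$n_clonal) else integer(0)
    clone_of <- sort(clone_of)
    n_cells <- c0$n_clonal + c0$n_nonclonal
    cell_id <- sprintf("cell_%05d", seq_len(n_cells))
    founder_sets <- lapply(seq_len(c0$n_clones), function(i) sample.int(M, k))
    true_guides <- vector("list", n_cells)
    ii <- jj <- xx <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      g <- if (i <= c0$n_clonal) {
        fs <- founder_sets[[clone_of[i]]]
        shared <- fs[sample.int(k, n_shared)]
        c(shared, sample(setdiff(seq_len(M), shared), k - n_shared))
      } else {
        sample.int(M, k)
      }
      u <- stats::rnbinom(k, mu = c0$umi_mean, size = 1 / c0$umi_dispersion)
      amb_n <- stats::rpois(1, c0$ambient_guides)
      amb_g <- if (amb_n > 0) sample.int(M, min(amb_n, M)) else integer(0)
      amb_u <- sample(1:2, length(amb_g), replace = TRUE, prob = c(0.8, 0.2))
      true_guides[[i]] <- sort(g[u > 0])
      jj[[i]] <- c(g, amb_g)
      xx[[i]] <- c(u, amb_u)
      ii[[i]] <- rep(i, k + length(amb_g))
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = unlist(xx),
      dims = c(n_cells, M),
      dimnames = list(cell_id, sprintf("sg%05d", seq_len(M))))
    truth <- data.frame(
      cell_id = cell_id,
      clone = c(sprintf("clone_%02d", clone_of),
                rep(NA_character_, c0$n_nonclonal)),
      is_doublet = FALSE,
      stringsAsFactors = FALSE)
    structure(list(counts = Matrix::drop0(counts), truth = structure(
      truth, founder_sets = founder_sets, true_guides = true_guides,
      config = c0, class = c("sim_truth", "data.frame"))))
  })
}

#' Merge random cell pairs into simulated doublets
#'
#' Replaces selected pairs of cells by a single merged barcode whose guide
#' UMI vector is the sum (guide set the union) of the pair, emulating a
#' droplet containing two cells. `fraction` is the fraction of the final
#' barcodes that are doublets.
#'
#' @param counts Cells x guides matrix from [simulate_population()].
#' @param truth The matching `sim_truth`.
#' @param fraction Fraction of output barcodes that are merged doublets.
#' @param pairing `"random"` pairs any two cells; `"distinct_clones"` pairs
#'   cells from two different planted clones (the detectable case — a merge
#'   of two same-clone cells is indistinguishable from a member by
#'   construction).
#' @param seed Random seed.
#' @return List with updated `counts` and `truth` (doublet rows flagged).
#' @export
simulate_doublets <- function(counts, truth, fraction = 0.05,
                              pairing = c("random", "distinct_clones"),
                              seed = 1) {
  pairing <- match.arg(pairing)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(counts)
  n_dbl <- round(fraction * n)
  if (n_dbl == 0L) return(list(counts = counts, truth = truth))
  .with_local_seed(seed, {
    pool <- if (pairing == "distinct_clones") which(!is.na(truth$clone)) else seq_len(n)
    pick <- integer(0)
    if (pairing == "distinct_clones") {
      # draw pairs until each pair spans two clones
      cand <- sample(pool)
      lab <- truth$clone[cand]
      used <- logical(length(cand))
      pairs <- matrix(0L, 2L, 0L)
      i <- 1L
      while (ncol(pairs) < n_dbl && i < length(cand)) {
        if (!used[i]) {
          j <- which(!used & lab != lab[i] & seq_along(cand) > i)[1L]
          if (!is.na(j)) {
            pairs <- cbind(pairs, c(cand[i], cand[j]))
            used[c(i, j)] <- TRUE
          }
        }
        i <- i + 1L
      }
    } else {
      pick <- sample(pool, 2L * n_dbl)
      pairs <- matrix(pick, nrow = 2L)
    }
    if (ncol(pairs) < n_dbl) {
      warning("only ", ncol(pairs), " doublet pairs could be formed")
    }
    merged <- counts[pairs[1L, ], , drop = FALSE] +
      counts[pairs[2L, ], , drop = FALSE]
    rownames(merged) <- sprintf("doublet_%04d", seq_len(ncol(pairs)))
    keep <- setdiff(seq_len(n), as.vector(pairs))
    out_counts <- rbind(counts[keep, , drop = FALSE], merged)
    out_truth <- rbind(
      truth[keep, ],
      data.frame(cell_id = rownames(merged), clone = NA_character_,
                 is_doublet = TRUE, stringsAsFactors = FALSE))
    rownames(out_truth) <- NULL
    attributes(out_truth)[c("founder_sets", "config")] <-
      attributes(truth)[c("founder_sets", "config")]
    class(out_truth) <- class(truth)
    list(counts = out_counts, truth = out_truth)
  })
}

#' Synthetic gene annotation on a toy genome
#'
#' Evenly spaced genes across a declared set of chromosomes, for driving the
#' copy-number and differential-expression simulators.
#'
#' @param n_genes Total genes.
#' @param chromosomes Chromosome labels (genes split evenly, in order).
#' @param spacing Base pairs between gene starts (default 1e5).
#' @return A `gene_annotation` data.frame (0-based starts).
#' @export
simulate_gene_annotation <- function(n_genes = 2000,
                                     chromosomes = paste0("chr", 1:10),
                                     spacing = 1e5) {
  per <- rep(seq_along(chromosomes), length.out = n_genes)
  per <- sort(per)
  pos <- unlist(lapply(table(per), function(m) (seq_len(m) - 1L) * spacing))
  ann <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = chromosomes[per],
    start = as.numeric(pos),
    end = as.numeric(pos) + spacing / 2,
    strand = "*",
    stringsAsFactors = FALSE)
  structure(ann, chromosome_order = chromosomes,
            class = c("gene_annotation", "data.frame"))
}

#' Simulate expression counts with planted segmental copy-number changes
#'
#' Baseline per-gene means are log-normal; counts are negative binomial. For
#' every row of `cnv_spec`, genes whose start falls inside the given
#' chromosome interval have their mean multiplied by `fold_change` in the
#' cells of the given clone (0.5 emulates a monoallelic loss, 1.5 a gain).
#'
#' @param clone_labels Character vector, one label per cell (`NA` = no clone);
#'   names (or the vector order) give the cell ids.
#' @param annotation A `gene_annotation` (e.g. [simulate_gene_annotation()]).
#' @param cnv_spec `data.frame` with columns `clone`, `chrom`, `start`, `end`,
#'   `fold_change`; may be empty for a null dataset.
#' @param base_mean Mean of the log-normal baseline gene means, in UMIs per
#'   gene per cell (default 8: a 2000-gene panel of well-expressed genes at
#'   ~16k UMIs/cell, typical droplet-sequencing depth after keeping robustly
#'   detected genes).
#' @param sdlog Log-scale spread of baseline gene means (default 0.5).
#' @param dispersion Negative-binomial dispersion (default 0.15).
#' @param seed Random seed.
#' @return Sparse cells x genes UMI matrix.
#' @export
simulate_expression_with_cnv <- function(clone_labels, annotation,
                                         cnv_spec = NULL, base_mean = 8,
                                         sdlog = 0.5, dispersion = 0.15,
                                         seed = 1) {
  stopifnot(inherits(annotation, "gene_annotation"))
  cells <- names(clone_labels)
  if (is.null(cells)) cells <- sprintf("cell_%05d", seq_along(clone_labels))
  n_genes <- nrow(annotation)
  if (!is.null(cnv_spec) && nrow(cnv_spec)) {
    bad <- !cnv_spec$chrom %in% annotation$chrom
    if (any(bad)) {
      stop("cnv_spec segment(s) on unannotated chromosome(s): ",
           paste(unique(cnv_spec$chrom[bad]), collapse = ", "))
    }
  }
  .with_local_seed(seed, {
    mu_g <- stats::rlnorm(n_genes, meanlog = log(base_mean) - sdlog^2 / 2,
                          sdlog = sdlog)
    fc <- matrix(1, length(cells), n_genes)
    if (!is.null(cnv_spec) && nrow(cnv_spec)) {
      for (s in seq_len(nrow(cnv_spec))) {
        gsel <- annotation$chrom == cnv_spec$chrom[s] &
          annotation$start >= cnv_spec$start[s] &
          annotation$start < cnv_spec$end[s]
        csel <- !is.na(clone_labels) & clone_labels == cnv_spec$clone[s]
        fc[csel, gsel] <- fc[csel, gsel] * cnv_spec$fold_change[s]
      }
    }
    mu <- sweep(fc, 2L, mu_g, `*`)
    x <- stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
    counts <- Matrix::Matrix(matrix(x, length(cells), n_genes,
                                    dimnames = list(cells, annotation$gene_id)),
                             sparse = TRUE)
    methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  })
}

#' Compare a clone assignment against simulation ground truth
#'
#' Clustering recovery metrics: adjusted Rand index between the planted and
#' inferred partitions (non-clonal and doublet cells each count as their own
#' singleton cluster), precision and recall on co-clonal cell pairs, and
#' doublet flagging sensitivity/specificity.
#'
#' @param truth `sim_truth` from the simulators.
#' @param assignment `clone_assignment` from [group_clones()].
#' @return List with `ari`, `pair_precision`, `pair_recall`,
#'   `doublet_sensitivity`, `doublet_specificity` (the last two `NA` when the
#'   truth has no / only doublets).
#' @export
evaluate_recovery <- function(truth, assignment) {
  m <- match(assignment$cell_id, truth$cell_id)
  if (anyNA(m)) stop("assignment contains cells absent from the truth")
  if (length(m) != nrow(truth)) stop("truth and assignment cell sets differ")
  truth <- truth[m, ]
  t_lab <- ifelse(is.na(truth$clone) | truth$is_doublet,
                  paste0(".single_t", seq_len(nrow(truth))), truth$clone)
  p_lab <- ifelse(assignment$is_doublet,
                  paste0(".dbl_p", seq_len(nrow(assignment))),
                  paste0("c", assignment$clone))
  ari <- mclust::adjustedRandIndex(t_lab, p_lab)
  # pair counts from the contingency table
  tab <- table(t_lab, p_lab)
  n_pairs <- function(v) sum(choose(v[v >= 2L], 2L))
  t_sizes <- table(t_lab[!startsWith(t_lab, ".single_t")])
  p_sizes <- table(p_lab[!startsWith(p_lab, ".dbl_p")])
  tp <- sum(choose(tab[tab >= 2L], 2L))
  true_pairs <- n_pairs(as.integer(t_sizes))
  pred_pairs <- n_pairs(as.integer(p_sizes))
  # of the predicted co-clonal pairs, those also truly co-clonal:
  joint <- table(paste(t_lab, p_lab))  # equals tab cells; tp computed above
  list(
    ari = ari,
    pair_precision = if (pred_pairs > 0) tp / pred_pairs else NA_real_,
    pair_recall = if (true_pairs > 0) tp / true_pairs else NA_real_,
    doublet_sensitivity = if (any(truth$is_doublet))
      mean(assignment$is_doublet[truth$is_doublet]) else NA_real_,
    doublet_specificity = if (any(!truth$is_doublet))
      mean(!assignment$is_doublet[!truth$is_doublet]) else NA_real_
  )
}
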