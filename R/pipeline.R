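#' Build a pipeline run configuration
#'
#' Collects every knob of an end-to-end run — input paths (or a simulation
#' preset), thresholds, ordering/comparison modes and seeds — into a plain
#' serializable list. A run writes its configuration next to its outputs, so
#' re-running the written YAML against the same inputs reproduces the
#' deterministic outputs byte-identically.
#'
#' @param guide_matrix,barcodes,features Paths to the guide count matrix
#'   inputs (ignored when `simulate` is given).
#' @param expression_matrix,expression_barcodes,expression_features Optional
#'   expression matrix inputs for the CNV stage.
#' @param annotation Optional gene annotation path (BED/GTF) for CNV / DE
#'   ordering.
#' @param region_map Optional sgRNA -> region TSV for the DE stage.
#' @param simulate Optional list of [sim_config()] arguments; when given, the
#'   guide matrix (and truth) are simulated instead of read.
#' @param alpha,order,compare,bonferroni Passed to [group_clones()].
#' @param major_size Major-clone size threshold (see [summarize_clones()]).
#' @param min_cell_fraction Expression filter (see [filter_low_expressed()]).
#' @param n_randomizations DE background randomizations.
#' @param seed Seed for every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(guide_matrix = NULL, barcodes = NULL, features = NULL,
                       expression_matrix = NULL, expression_barcodes = NULL,
                       expression_features = NULL, annotation = NULL,
                       region_map = NULL, simulate = NULL,
                       alpha = 0.05, order = "umi_asc", compare = "founder",
                       bonferroni = "tests", major_size = 100,
                       min_cell_fraction = 0.10, n_randomizations = 10000,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulate) && is.null(cfg$guide_matrix)) {
    stop("either a guide matrix path or a simulation preset is required")
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `write_run_config`: invisibly `path`; `read_run_config`: the
#'   configuration (round-trips: `read(write(x))` equals `x`).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full clone-calling pipeline
#'
#' Executes the stages in dependency order: load or simulate the guide
#' matrix, detect guides per cell, group cells into clones, summarize clones,
#' then (inputs permitting) build clone copy-number profiles and region-level
#' differential expression. Writes `clones.tsv`, `clone_table.tsv` and, when
#' run, `cnv_profiles.tsv` and `de.tsv`, plus `config.yaml`, a JSON
#' `manifest.json` and a JSON-lines `log.jsonl` with per-stage counts (cells
#' in, doublets, Bonferroni denominator, iteration order) so every run is
#' auditable. Fails fast if a declared input file is missing.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @param quiet Suppress progress messages.
#' @return The manifest (named list of stage outputs), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$guide_matrix, config$barcodes, config$features,
              config$expression_matrix, config$annotation, config$region_map)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    if (!quiet) message(sprintf("[%s] %s", stage,
                                paste(names(rec)[-1L], unlist(rec[-1L]),
                                      sep = "=", collapse = " ")))
  }
  manifest <- list(config = file.path(out_dir, "config.yaml"))
  write_run_config(config, manifest$config)

  if (!is.null(config$simulate)) {
    sim <- simulate_population(do.call(sim_config, c(
      config$simulate, if (!("seed" %in% names(config$simulate)))
        list(seed = config$seed))))
    counts <- sim$counts
    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$truth <- truth_path
    log_stage("simulate", cells = nrow(counts), guides = ncol(counts))
  } else {
    counts <- read_guide_matrix(config$guide_matrix, config$barcodes,
                                config$features)
    log_stage("load", cells = nrow(counts), guides = ncol(counts))
  }

  sets <- detect_guides(counts)
  st <- guide_detection_stats(sets)
  log_stage("detect", mean_guides = round(st$mean_guides_per_cell, 2),
            mean_umi = round(st$mean_umi_per_guide, 2))

  assignment <- group_clones(sets, alpha = config$alpha, order = config$order,
                             compare = config$compare,
                             bonferroni = config$bonferroni)
  tab <- summarize_clones(assignment, sets, major_size = config$major_size,
                          seed = config$seed)
  log_stage("clones", clones = nrow(tab), doublets = attr(tab, "n_doublets"),
            clonal_fraction = round(attr(tab, "clonal_fraction"), 4),
            bonferroni_denominator = attr(assignment, "denominator"),
            order = attr(assignment, "order"))
  clone_df <- data.frame(
    cell_id = assignment$cell_id,
    clone_id = assignment$clone,
    clone_size = ifelse(assignment$is_doublet, NA_integer_,
                        tab$size[assignment$clone]),
    is_doublet = assignment$is_doublet,
    is_major = ifelse(assignment$is_doublet, FALSE,
                      tab$is_major[assignment$clone]),
    best_log10p = assignment$best_log10p,
    stringsAsFactors = FALSE)
  manifest$clones <- file.path(out_dir, "clones.tsv")
  utils::write.table(clone_df, manifest$clones, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$clone_table <- file.path(out_dir, "clone_table.tsv")
  utils::write.table(tab, manifest$clone_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(config$expression_matrix) && !is.null(config$annotation)) {
    expr <- read_expression_matrix(config$expression_matrix,
                                   config$expression_barcodes,
                                   config$expression_features)
    ann <- read_gene_annotation(config$annotation)
    expr <- expr[intersect(rownames(expr), assignment$cell_id), , drop = FALSE]
    z <- gene_zscore(cpm_normalize(
      filter_low_expressed(expr, config$min_cell_fraction)))
    prof <- clone_mean_profile(z, assignment, ann)
    manifest$cnv_profiles <- file.path(out_dir, "cnv_profiles.tsv")
    utils::write.table(
      data.frame(clone = rep(rownames(prof$profiles),
                             each = ncol(prof$profiles)),
                 gene_id = rep(prof$genes$gene_id,
                               times = nrow(prof$profiles)),
                 chrom = rep(prof$genes$chrom, times = nrow(prof$profiles)),
                 mean_z = as.vector(t(prof$profiles)),
                 stringsAsFactors = FALSE),
      manifest$cnv_profiles, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("cnv", clones = nrow(prof$profiles), genes = ncol(prof$profiles))
    if (!is.null(config$region_map)) {
      rmap <- read_region_map(config$region_map)
      groups <- cells_for_region(rmap, sets)
      de <- region_de(expr, groups,
                      n_randomizations = config$n_randomizations,
                      seed = config$seed)
      manifest$de <- file.path(out_dir, "de.tsv")
      utils::write.table(manhattan_table(de, ann), manifest$de, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_stage("de", regions = length(unique(de$region_id)),
                genes = length(unique(de$gene_id)))
    }
  }

  manifest$log <- log_path
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("done", outputs = length(manifest))
  invisible(manifest)
}
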