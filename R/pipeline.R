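#' Default pipeline run configuration
#'
#' Nested key-value configuration consumed by [run_pipeline()]. Every
#' analysis threshold is a named key so that threshold sensitivity is
#' visible and overridable. The `thresholds` section defaults to the
#' synthetic-platform calibration (screen cutoffs at +/-0.50 seg.mean,
#' the single-copy gain/loss scale the simulator emits); the published
#' array defaults remain available through [threshold_config()].
#'
#' @param ... overrides for any top-level key or nested section
#'   (`simulation`, `thresholds`); unknown keys are an error.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  config <- list(
    simulation = list(),               # overrides for simulation_config()
    thresholds = list(high_screen_threshold = 0.5,
                      low_screen_threshold = -0.5),
    quantile_q = 0.25,
    bootstrap_reps = 50,
    fdr_level = 0.05,
    extreme_fraction = 0.10,
    min_correlation_pairs = 5,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(config))
    if (length(bad) > 0) stop_input("unknown config key '%s'", bad[1])
    for (key in names(overrides)) {
      if (key %in% c("simulation", "thresholds")) {
        known <- names(formals(if (key == "simulation") simulation_config
                               else threshold_config))
        bad2 <- setdiff(names(overrides[[key]]), known)
        if (length(bad2) > 0) {
          stop_input("unknown config key '%s$%s'", key, bad2[1])
        }
        config[[key]] <- utils::modifyList(config[[key]], overrides[[key]])
      } else {
        config[[key]] <- overrides[[key]]
      }
    }
  }
  structure(config, class = "run_config")
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end on one output directory, each stage
#' reading the artifacts of the previous one and writing new files (no
#' stage mutates its inputs). A `manifest.json` records, per stage, the
#' seed, a configuration hash, every artifact with row count and md5, and
#' the counts in/out of every filter. Reruns with the same configuration
#' and seed reproduce all artifacts byte-identically.
#'
#' Stages: `simulate` writes a synthetic cohort's input files; `assign`
#' builds the gene x sample CNV matrix under the containment and
#' marker-count rules, trims near-zero cells, classifies states, tallies
#' alteration frequencies and extracts breakpoints; `associate` runs the
#' rank-sum CNV screen, both correlation screens, the normal-deviation
#' filter, the binned expression profile and the CDF gap; `classify`
#' computes tumor:normal ratios, quantile thresholds, feature quadrants,
#' per-gene significance against normals and percentile ranks; `enrich`
#' tests each feature class for gene-set over-representation; `all`
#' chains every stage.
#'
#' @param stage one of `"simulate"`, `"assign"`, `"associate"`,
#'   `"classify"`, `"enrich"`, `"all"`.
#' @param config a [default_run_config()] (or overrides list).
#' @param outdir working/output directory.
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "assign", "associate",
                                   "classify", "enrich"),
                         config = default_run_config(), outdir, seed = NULL) {
  stage <- match.arg(stage)
  if (!inherits(config, "run_config")) {
    config <- do.call(default_run_config, as.list(config))
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "assign", "associate", "classify", "enrich")
  } else stage
  manifest <- read_manifest(outdir)
  for (st in stages) {
    entry <- switch(st,
      simulate = stage_simulate(config, outdir),
      assign = stage_assign(config, outdir),
      associate = stage_associate(config, outdir),
      classify = stage_classify(config, outdir),
      enrich = stage_enrich(config, outdir)
    )
    entry$stage <- st
    entry$seed <- config$seed
    entry$config_hash <- rlang::hash(unclass(config))
    manifest[[st]] <- entry[c("stage", "seed", "config_hash",
                              setdiff(names(entry), c("stage", "seed", "config_hash")))]
    write_manifest(manifest, outdir)
    message(sprintf("[%s] done: %s", st,
                    paste(names(entry$files), collapse = ", ")))
  }
  invisible(manifest)
}

read_manifest <- function(outdir) {
  path <- file.path(outdir, "manifest.json")
  if (file.exists(path)) jsonlite::read_json(path) else list()
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

file_entry <- function(path) {
  n <- length(readLines(path))
  list(rows = n, md5 = unname(md5sum(path)))
}

files_entry <- function(paths) {
  out <- lapply(paths, file_entry)
  names(out) <- basename(unlist(paths))
  out
}

require_input <- function(outdir, name) {
  path <- file.path(outdir, name)
  if (!file.exists(path)) {
    stop_input("stage input '%s' not found in %s; run the earlier stage first",
               name, outdir)
  }
  path
}

stage_simulate <- function(config, outdir) {
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  cohort <- generate_cohort(do.call(simulation_config, sim_args))
  paths <- write_cohort(cohort, outdir)
  list(files = files_entry(as.list(paths)),
       counts = list(
         genes = nrow(cohort$annotation),
         tumor_samples = cohort$config$n_tumor,
         normal_samples = cohort$config$n_normal,
         planted_genes = sum(cohort$truth$class != "null"),
         segments = nrow(cohort$segments)
       ))
}

load_inputs <- function(outdir) {
  groups <- read_sample_groups(require_input(outdir, "sample_groups.tsv"))
  list(
    groups = groups,
    annotation = read_bed(require_input(outdir, "genes.bed")),
    segments = read_segments(require_input(outdir, "segments.seg")),
    meth = read_matrix(require_input(outdir, "methylation.tsv"), "methylation",
                       sample_groups = groups),
    expr_tumor = read_matrix(require_input(outdir, "expression_tumor.tsv"),
                             "expression", sample_groups = groups),
    expr_normal = read_matrix(require_input(outdir, "expression_normal.tsv"),
                              "expression", sample_groups = groups)
  )
}

tumor_cols <- function(m, groups) {
  intersect(colnames(m), groups$sample_id[groups$group == "tumor"])
}

stage_assign <- function(config, outdir) {
  inp <- load_inputs(outdir)
  thr <- do.call(threshold_config, config$thresholds)
  cnv_all <- assign_segments_to_genes(inp$segments, inp$annotation, thr)
  filter_counts <- attr(cnv_all, "filter_counts")
  cnv <- cnv_all[, tumor_cols(cnv_all, inp$groups), drop = FALSE]
  n_before <- sum(!is.na(cnv))
  cnv <- trim_near_zero(cnv, thr$near_zero_trim)
  n_after <- sum(!is.na(cnv))
  states <- classify_cnv_state(cnv, thr)
  freq <- alteration_frequency(states)
  bp <- extract_breakpoints(
    inp$segments[inp$segments$sample %in% tumor_cols(cnv_all, inp$groups), ],
    thr)
  meth_rank <- methylation_tumor_normal_ranking(inp$meth, inp$groups,
                                                config$extreme_fraction)
  paths <- list(
    cnv = file.path(outdir, "cnv_matrix.tsv"),
    states = file.path(outdir, "cnv_states.tsv"),
    freq = file.path(outdir, "alteration_frequency.tsv"),
    breakpoints = file.path(outdir, "breakpoints.tsv"),
    meth_ranking = file.path(outdir, "methylation_ranking.tsv")
  )
  write_matrix(cnv, paths$cnv)
  write_state_matrix(states, paths$states)
  write_tsv(freq, paths$freq)
  write_tsv(bp, paths$breakpoints)
  write_tsv(meth_rank, paths$meth_ranking)
  list(files = files_entry(paths),
       counts = list(
         cells_excluded_split = unname(filter_counts[["split"]]),
         cells_excluded_partial_or_uncovered =
           unname(filter_counts[["partial_or_uncovered"]]),
         cells_excluded_low_num_info = unname(filter_counts[["low_num_info"]]),
         cells_before_trim = n_before,
         cells_after_trim = n_after,
         breakpoints = nrow(bp)
       ))
}

write_state_matrix <- function(states, path) {
  df <- data.frame(gene_id = rownames(states), states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

stage_associate <- function(config, outdir) {
  inp <- load_inputs(outdir)
  thr <- do.call(threshold_config, config$thresholds)
  cnv <- read_matrix(require_input(outdir, "cnv_matrix.tsv"), "cnv")
  screen <- wilcoxon_cnv_screen(inp$expr_tumor, cnv, thr)
  cor_cnv <- per_gene_correlation(cnv, inp$expr_tumor,
                                  min_pairs = config$min_correlation_pairs)
  meth_t <- inp$meth[, tumor_cols(inp$meth, inp$groups), drop = FALSE]
  cor_meth <- per_gene_correlation(meth_t, inp$expr_tumor,
                                   min_pairs = config$min_correlation_pairs,
                                   flip_x = TRUE)
  deviation <- normal_deviation_filter(inp$expr_tumor, cnv, inp$expr_normal, thr)
  states <- classify_cnv_state(cnv, thr)
  shared_g <- intersect(rownames(cnv), rownames(inp$expr_tumor))
  shared_s <- intersect(colnames(cnv), colnames(inp$expr_tumor))
  st <- states[shared_g, shared_s, drop = FALSE]
  ex <- inp$expr_tumor[shared_g, shared_s, drop = FALSE]
  gap <- if (any(st == "deleted", na.rm = TRUE) &&
             any(st == "amplified", na.rm = TRUE)) {
    cnv_expression_cdf_gap(ex[which(st == "deleted")],
                           ex[which(st == "amplified")])
  } else NA_real_
  obs <- cnv[!is.na(cnv)]
  edges <- seq(floor(min(obs) * 4) / 4, ceiling(max(obs) * 4) / 4, by = 0.25)
  bins <- expression_by_cnv_bins(inp$expr_tumor, cnv, edges)
  paths <- list(
    screen = file.path(outdir, "wilcoxon_screen.tsv"),
    cor_cnv = file.path(outdir, "correlation_cnv_expr.tsv"),
    cor_meth = file.path(outdir, "correlation_meth_expr.tsv"),
    deviation = file.path(outdir, "normal_deviation.tsv"),
    bins = file.path(outdir, "expression_by_cnv_bins.tsv")
  )
  write_tsv(screen, paths$screen)
  write_tsv(cor_cnv, paths$cor_cnv)
  write_tsv(cor_meth, paths$cor_meth)
  write_tsv(deviation, paths$deviation)
  write_tsv(bins, paths$bins)
  list(files = files_entry(paths),
       counts = list(
         genes_tested = sum(!is.na(screen$p_value)),
         genes_skipped = sum(is.na(screen$p_value)),
         genes_significant = sum(screen$q_value < config$fdr_level, na.rm = TRUE),
         deviation_retained = sum(deviation$retained)
       ),
       cdf_gap = gap)
}

stage_classify <- function(config, outdir) {
  inp <- load_inputs(outdir)
  thr <- do.call(threshold_config, config$thresholds)
  cnv <- read_matrix(require_input(outdir, "cnv_matrix.tsv"), "cnv")
  ratios <- tumor_normal_expression_ratio(
    inp$expr_tumor, inp$expr_normal,
    bootstrap_reps = config$bootstrap_reps, seed = config$seed)
  meth_t <- inp$meth[, tumor_cols(inp$meth, inp$groups), drop = FALSE]
  meth_gene <- rowMeans(meth_t, na.rm = TRUE)
  thresholds <- compute_quantile_thresholds(ratios$ratio, meth_gene,
                                            q = config$quantile_q)
  calls <- classify_features(cnv, inp$meth, ratios, thresholds, thr)
  sig <- normal_vs_tumor_significance(
    inp$meth, cbind(inp$expr_tumor, inp$expr_normal), inp$groups)
  sig <- percentile_rank_calls(sig, config$fdr_level)
  calls <- merge(calls, sig, by = "gene_id", all.x = TRUE, sort = TRUE)
  calls <- calls[order(calls$gene_id, calls$cnv_class), ]
  ranked <- sig[!is.na(sig$percentile_rank), c("gene_id", "percentile_rank")]
  ann <- inp$annotation
  ranked <- merge(ranked, data.frame(
    gene_id = ann$gene_id, chrom = ann$chrom,
    midpoint = (ann$start + ann$end) / 2, stringsAsFactors = FALSE
  ), by = "gene_id", sort = TRUE)
  ranked <- ranked[order(ranked$chrom, ranked$midpoint),
                   c("gene_id", "chrom", "midpoint", "percentile_rank")]
  paths <- list(
    ratios = file.path(outdir, "expression_ratios.tsv"),
    calls = file.path(outdir, "feature_calls.tsv"),
    significance = file.path(outdir, "significance.tsv"),
    ranking = file.path(outdir, "percentile_ranking.tsv")
  )
  write_tsv(ratios, paths$ratios)
  write_tsv(calls, paths$calls)
  write_tsv(sig, paths$significance)
  write_tsv(ranked, paths$ranking)
  list(files = files_entry(paths),
       counts = list(
         extreme_amplified = sum(calls$cnv_class == "amplified"),
         extreme_deleted = sum(calls$cnv_class == "deleted"),
         feature_calls = sum(calls$feature_class != "none"),
         significant_genes = sum(sig$q_multi < config$fdr_level, na.rm = TRUE)
       ),
       quantile_thresholds = thresholds)
}

stage_enrich <- function(config, outdir) {
  inp <- load_inputs(outdir)
  cnv <- read_matrix(require_input(outdir, "cnv_matrix.tsv"), "cnv")
  calls_path <- require_input(outdir, "feature_calls.tsv")
  calls <- read.delim(calls_path, stringsAsFactors = FALSE)
  gene_sets <- read_gmt(require_input(outdir, "gene_sets.gmt"))
  # universe: genes observed in all three modalities
  universe <- Reduce(intersect, list(
    rownames(cnv)[rowSums(!is.na(cnv)) > 0],
    rownames(inp$meth)[rowSums(!is.na(inp$meth)) > 0],
    rownames(inp$expr_tumor)[rowSums(!is.na(inp$expr_tumor)) > 0]
  ))
  classes <- setdiff(unique(calls$feature_class), "none")
  rows <- lapply(sort(classes), function(cl) {
    genes <- unique(calls$gene_id[calls$feature_class == cl])
    genes <- intersect(genes, universe)
    if (length(genes) == 0) return(NULL)
    res <- hypergeometric_enrichment(genes, gene_sets, universe,
                                     config$fdr_level)
    cbind(feature_class = cl, res, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(feature_class = character(), set_id = character(),
               k = integer(), K = integer(), n = integer(), N = integer(),
               p_value = numeric(), q_value = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  }
  path <- file.path(outdir, "enrichment.tsv")
  write_tsv(out, path)
  list(files = files_entry(list(enrichment = path)),
       counts = list(
         universe_size = length(universe),
         classes_tested = length(rows),
         sets_significant = sum(out$significant)
       ))
}
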