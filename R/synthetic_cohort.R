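#' Simulation configuration for a synthetic multi-omics cohort
#'
#' Parameterizes [generate_cohort()]. The defaults mirror the structure of
#' a serous ovarian tumor cohort profiled on segmented copy-number,
#' promoter-methylation and expression arrays: 42 tumors and 7 tissue
#' normals, genes tiled over 22 chromosomes, and planted gene classes
#' exhibiting the four canonical feature quadrants (amplified /
#' hypomethylated / overexpressed oncogene-like genes; deleted /
#' hypermethylated / underexpressed tumor-suppressor-like genes; and the
#' two cross classes).
#'
#' @param n_genes number of simulated genes.
#' @param n_tumor,n_normal tumor and normal sample counts
#'   (`n_tumor >= 2`, `n_normal >= 1`).
#' @param n_chromosomes number of chromosomes genes are tiled onto.
#' @param planted_fractions named numeric vector giving the fraction of
#'   genes planted per feature class; names from `oncogene_like`,
#'   `ts_like`, `amplified_suppressed`, `deleted_expressed`. Fractions must
#'   sum to at most 1; the remainder is null. Planted counts are
#'   `round(fraction * n_genes)` with half rounded up.
#' @param cnv_effect mean absolute seg.mean shift of an altered gene
#'   (log2 copy-ratio units).
#' @param expr_dosage_slope log2-expression change per unit seg.mean.
#' @param meth_effect methylation shift (platform units) applied to
#'   hyper-/hypomethylated planted classes.
#' @param meth_coupling log2-expression decrease per unit of methylation
#'   above the platform center (the repressive promoter-methylation term).
#' @param noise_sd named numeric vector of Gaussian noise SDs per modality:
#'   `cnv` (seg.mean units), `meth` (platform units), `expr` (log2 units).
#' @param methylation_dialect `"moma_ratio"` (scores centered at 1.0,
#'   higher = more methylated) or `"beta"` (values clipped to
#'   \[0.01, 0.99\], centered at 0.5).
#' @param altered_sample_fraction fraction of tumor samples carrying each
#'   planted alteration.
#' @param effect_mult_range length-2 range of the per-gene multiplier
#'   applied to `cnv_effect`, giving genes a continuum of realized
#'   aberration magnitudes rather than a single spike.
#' @param cnv_flip_prob probability that an individual carrier sample's
#'   copy-number alteration flips sign (a gene amplified in some tumors and
#'   deleted in others); methylation and the dosage term follow the flipped
#'   seg.mean, the planted methylation shift does not.
#' @param normal_cnv_sd seg.mean SD of the neutral/normal copy state.
#' @param expr_baseline_range log2-expression baseline range genes are
#'   drawn from (uniform).
#' @param seed integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_tumor = 42,
                              n_normal = 7,
                              n_chromosomes = 22,
                              planted_fractions = c(oncogene_like = 0.05,
                                                    ts_like = 0.05,
                                                    amplified_suppressed = 0.02,
                                                    deleted_expressed = 0.02),
                              cnv_effect = 1.0,
                              expr_dosage_slope = 1.0,
                              meth_effect = 0.3,
                              meth_coupling = 1.0,
                              noise_sd = c(cnv = 0.1, meth = 0.05, expr = 0.3),
                              methylation_dialect = c("moma_ratio", "beta"),
                              altered_sample_fraction = 0.5,
                              effect_mult_range = c(0.6, 1.4),
                              cnv_flip_prob = 0,
                              normal_cnv_sd = 0.02,
                              expr_baseline_range = c(5, 10),
                              seed = 1L) {
  methylation_dialect <- match.arg(methylation_dialect)
  classes <- c("oncogene_like", "ts_like", "amplified_suppressed", "deleted_expressed")
  if (length(planted_fractions) > 0) {
    if (is.null(names(planted_fractions)) ||
        !all(names(planted_fractions) %in% classes)) {
      stop_input("planted_fractions must be named with feature classes: %s",
                 paste(classes, collapse = ", "))
    }
    if (any(planted_fractions < 0 | planted_fractions > 1)) {
      stop_input("planted_fractions must lie in [0, 1]")
    }
    if (sum(planted_fractions) > 1 + 1e-12) {
      stop_input("planted_fractions must sum to at most 1 (got %g)",
                 sum(planted_fractions))
    }
  }
  full <- setNames(numeric(length(classes)), classes)
  full[names(planted_fractions)] <- planted_fractions
  if (!is_count(n_genes) || n_genes < 1) stop_input("n_genes must be a positive integer")
  if (!is_count(n_tumor) || n_tumor < 2) stop_input("n_tumor must be >= 2")
  if (!is_count(n_normal) || n_normal < 1) stop_input("n_normal must be >= 1")
  if (!is_count(n_chromosomes) || n_chromosomes < 1 || n_chromosomes > n_genes) {
    stop_input("n_chromosomes must be a positive integer <= n_genes")
  }
  if (!all(c("cnv", "meth", "expr") %in% names(noise_sd)) || any(noise_sd <= 0)) {
    stop_input("noise_sd needs positive entries named cnv, meth, expr")
  }
  if (altered_sample_fraction <= 0 || altered_sample_fraction > 1) {
    stop_input("altered_sample_fraction must lie in (0, 1]")
  }
  if (cnv_flip_prob < 0 || cnv_flip_prob > 1) {
    stop_input("cnv_flip_prob must lie in [0, 1]")
  }
  if (length(effect_mult_range) != 2 || any(effect_mult_range <= 0) ||
      effect_mult_range[1] > effect_mult_range[2]) {
    stop_input("effect_mult_range must be an increasing positive pair")
  }
  if (!is_count(seed)) stop_input("seed must be an integer")
  structure(list(
    n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal), n_chromosomes = as.integer(n_chromosomes),
    planted_fractions = full, cnv_effect = cnv_effect,
    expr_dosage_slope = expr_dosage_slope, meth_effect = meth_effect,
    meth_coupling = meth_coupling, noise_sd = noise_sd,
    methylation_dialect = methylation_dialect,
    altered_sample_fraction = altered_sample_fraction,
    effect_mult_range = effect_mult_range, cnv_flip_prob = cnv_flip_prob,
    normal_cnv_sd = normal_cnv_sd, expr_baseline_range = expr_baseline_range,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

meth_center <- function(dialect) {
  if (dialect == "beta") 0.5 else 1.0
}

# Direction of the planted CNV and methylation shifts per feature class.
class_signs <- function(class) {
  switch(class,
    oncogene_like        = c(cnv = +1, meth = -1),
    ts_like              = c(cnv = -1, meth = +1),
    amplified_suppressed = c(cnv = +1, meth = +1),
    deleted_expressed    = c(cnv = -1, meth = -1),
    c(cnv = 0, meth = 0)
  )
}

GENE_LENGTH <- 10000
GENE_GAP <- 10000

#' Generate a synthetic tumor/normal cohort with planted gene classes
#'
#' Simulates the statistical structure the downstream analysis assumes:
#' per-sample CBS-style segment tables in which every gene is fully
#' contained in exactly one segment, a methylation matrix over tumors and
#' normals, log2 expression matrices for tumors and normals, a BED-style
#' gene annotation, and the planted per-gene truth.
#'
#' Genes are tiled without overlap along `n_chromosomes` chromosomes. Each
#' planted gene receives a realized seg.mean effect
#' `sign * cnv_effect * U(effect_mult_range)` in a random
#' `altered_sample_fraction` of tumors (its carriers); carrier genes get
#' their own CBS segment, consecutive unaltered genes share a neutral
#' segment. Log2 expression follows
#' `baseline + expr_dosage_slope * seg.mean - meth_coupling * (methylation
#' - platform_center) + noise`, so dosage- and methylation-driven
#' expression changes arise mechanistically rather than being painted on.
#' Normal samples sit at seg.mean ~ 0, platform-center methylation and
#' baseline expression. The output is deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: a list with elements
#'   `segments` (tumor segment table, internal coordinates), `annotation`,
#'   `methylation` (genes x tumors+normals), `expr_tumor`, `expr_normal`,
#'   `cnv` (genes x tumors true per-gene seg.mean), `truth` (data.frame
#'   `gene_id`, `class`, `cnv_effect`, `meth_effect`, `n_carriers`,
#'   `carriers`), `sample_groups`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_input("config must come from simulation_config()")
  }
  set.seed(config$seed)
  n_genes <- config$n_genes
  tumors <- sprintf("T%03d", seq_len(config$n_tumor))
  normals <- sprintf("N%02d", seq_len(config$n_normal))
  center <- meth_center(config$methylation_dialect)

  # --- gene annotation: non-overlapping tiles, round-robin chromosome sizes
  per_chrom <- rep(n_genes %/% config$n_chromosomes, config$n_chromosomes)
  extra <- n_genes %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom_of <- rep(seq_len(config$n_chromosomes), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  starts <- GENE_GAP + (idx_in_chrom - 1) * (GENE_LENGTH + GENE_GAP)
  annotation <- data.frame(
    gene_id = gene_ids,
    chrom = paste0("chr", chrom_of),
    start = starts, end = starts + GENE_LENGTH,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE
  )
  chrom_len <- setNames((per_chrom) * (GENE_LENGTH + GENE_GAP) + GENE_GAP,
                        paste0("chr", seq_len(config$n_chromosomes)))

  # --- planted classes: round-half-up counts, remainder null
  counts <- round_half_up(config$planted_fractions * n_genes)
  if (sum(counts) > n_genes) {
    stop_input("planted fractions yield %d genes for %d available",
               sum(counts), n_genes)
  }
  class <- rep("null", n_genes)
  pool <- sample.int(n_genes)
  at <- 0
  for (cl in names(counts)) {
    if (counts[[cl]] > 0) {
      class[pool[at + seq_len(counts[[cl]])]] <- cl
      at <- at + counts[[cl]]
    }
  }

  planted <- which(class != "null")
  sign_cnv <- vapply(class, function(cl) class_signs(cl)[["cnv"]], numeric(1))
  sign_meth <- vapply(class, function(cl) class_signs(cl)[["meth"]], numeric(1))
  mult <- numeric(n_genes)
  mult[planted] <- runif(length(planted), config$effect_mult_range[1],
                         config$effect_mult_range[2])
  cnv_eff <- sign_cnv * config$cnv_effect * mult
  meth_eff <- sign_meth * config$meth_effect

  # carriers: logical genes x tumors; flips: carrier cells whose CNV sign inverts
  n_carr <- round_half_up(config$altered_sample_fraction * config$n_tumor)
  carrier <- matrix(FALSE, n_genes, config$n_tumor,
                    dimnames = list(gene_ids, tumors))
  for (g in planted) {
    carrier[g, sample.int(config$n_tumor, n_carr)] <- TRUE
  }
  flip <- carrier & matrix(runif(length(carrier)) < config$cnv_flip_prob,
                           n_genes, config$n_tumor)

  # --- per-sample segments; carrier genes get private segments, runs of
  # unaltered genes merge into one neutral segment
  cnv <- matrix(NA_real_, n_genes, config$n_tumor,
                dimnames = list(gene_ids, tumors))
  seg_list <- vector("list", config$n_tumor * config$n_chromosomes)
  k <- 0
  for (s in seq_len(config$n_tumor)) {
    for (ch in seq_len(config$n_chromosomes)) {
      idx <- which(chrom_of == ch)
      car <- carrier[idx, s]
      len <- length(idx)
      new_grp <- car | c(TRUE, car[-len])
      grp <- cumsum(new_grp)
      n_grp <- max(grp)
      grp_first <- match(seq_len(n_grp), grp)
      grp_len <- tabulate(grp, n_grp)
      grp_eff <- ifelse(car[grp_first],
                        cnv_eff[idx[grp_first]] *
                          ifelse(flip[idx, s][grp_first], -1, 1),
                        0)
      seg_val <- rnorm(n_grp, mean = grp_eff, sd = config$noise_sd[["cnv"]])
      num_info <- 5L + rpois(n_grp, 10 * grp_len)
      grp_last <- grp_first + grp_len - 1L
      first_start <- annotation$start[idx[grp_first]]
      last_end <- annotation$end[idx[grp_last]]
      seg_start <- c(0, (last_end[-n_grp] + first_start[-1]) / 2)
      seg_end <- c(seg_start[-1], chrom_len[[ch]])
      cnv[idx, s] <- seg_val[grp]
      k <- k + 1
      seg_list[[k]] <- data.frame(
        sample = tumors[s], chrom = paste0("chr", ch),
        start = seg_start, end = seg_end,
        num_info = num_info, seg_mean = seg_val,
        stringsAsFactors = FALSE
      )
    }
  }
  # normal samples: one neutral segment per chromosome (the reference state)
  norm_list <- vector("list", config$n_normal)
  for (s in seq_len(config$n_normal)) {
    norm_list[[s]] <- data.frame(
      sample = normals[s], chrom = paste0("chr", seq_len(config$n_chromosomes)),
      start = 0, end = unname(chrom_len),
      num_info = 5L + rpois(config$n_chromosomes, 10 * per_chrom),
      seg_mean = rnorm(config$n_chromosomes, 0, config$normal_cnv_sd),
      stringsAsFactors = FALSE
    )
  }
  segments <- do.call(rbind, c(seg_list[seq_len(k)], norm_list))
  rownames(segments) <- NULL

  # --- methylation: platform center + planted shift at carrier cells
  all_samples <- c(tumors, normals)
  meth <- matrix(rnorm(n_genes * length(all_samples), mean = center,
                       sd = config$noise_sd[["meth"]]),
                 n_genes, length(all_samples),
                 dimnames = list(gene_ids, all_samples))
  shift <- carrier * meth_eff          # genes x tumors
  meth[, tumors] <- meth[, tumors] + shift
  if (config$methylation_dialect == "beta") {
    meth <- pmin(pmax(meth, 0.01), 0.99)
  }

  # --- expression: dosage + repressive methylation coupling
  baseline <- runif(n_genes, config$expr_baseline_range[1],
                    config$expr_baseline_range[2])
  expr_tumor <- baseline +
    config$expr_dosage_slope * cnv -
    config$meth_coupling * (meth[, tumors] - center) +
    matrix(rnorm(n_genes * config$n_tumor, sd = config$noise_sd[["expr"]]),
           n_genes, config$n_tumor)
  dimnames(expr_tumor) <- list(gene_ids, tumors)
  expr_normal <- baseline +
    matrix(rnorm(n_genes * config$n_normal, sd = config$noise_sd[["expr"]]),
           n_genes, config$n_normal)
  dimnames(expr_normal) <- list(gene_ids, normals)

  truth <- data.frame(
    gene_id = gene_ids, class = class,
    cnv_effect = cnv_eff, meth_effect = meth_eff,
    n_carriers = as.integer(rowSums(carrier)),
    carriers = apply(carrier, 1, function(x) paste(tumors[x], collapse = ",")),
    stringsAsFactors = FALSE
  )

  structure(list(
    segments = segments,
    annotation = annotation,
    methylation = meth,
    expr_tumor = expr_tumor,
    expr_normal = expr_normal,
    cnv = cnv,
    truth = truth,
    sample_groups = data.frame(
      sample_id = all_samples,
      group = c(rep("tumor", config$n_tumor), rep("normal", config$n_normal)),
      stringsAsFactors = FALSE
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' Inject assignment-rule edge cases into a segment table
#'
#' Produces positive controls for the segment-to-gene exclusion rules:
#' splitting the segment covering a gene at the gene midpoint (the gene
#' then spans two segments and must come out missing) or forcing the
#' covering segment's marker count below the inclusion threshold.
#'
#' @param segments segment table (internal 0-based coordinates).
#' @param edits data.frame with columns `gene_id`, `sample_id`, `action`
#'   (`"split"` or `"low_num_info"`) and optional `num_info` (value used by
#'   `low_num_info`; default 3). An empty edit table is the identity.
#' @param annotation gene annotation locating each edited gene.
#' @return the edited segment table.
#' @export
inject_edge_cases <- function(segments, edits, annotation) {
  if (is.null(edits) || nrow(edits) == 0) return(segments)
  for (i in seq_len(nrow(edits))) {
    gene <- edits$gene_id[i]
    samp <- edits$sample_id[i]
    action <- edits$action[i]
    g <- annotation[annotation$gene_id == gene, ]
    if (nrow(g) == 0) stop_input("inject_edge_cases: unknown gene '%s'", gene)
    if (!samp %in% segments$sample) {
      stop_input("inject_edge_cases: unknown sample '%s'", samp)
    }
    hit <- which(segments$sample == samp & segments$chrom == g$chrom &
                   segments$start <= g$start & segments$end >= g$end)
    if (length(hit) == 0) {
      stop_input("inject_edge_cases: no segment covers gene '%s' in sample '%s'",
                 gene, samp)
    }
    hit <- hit[1]
    if (action == "split") {
      mid <- floor((g$start + g$end) / 2)
      left <- segments[hit, ]
      right <- segments[hit, ]
      left$end <- mid
      right$start <- mid
      # both halves keep ample marker support so only the split excludes
      left$num_info <- max(left$num_info, 4L)
      right$num_info <- max(right$num_info, 4L)
      segments <- rbind(segments[-hit, ], left, right)
    } else if (action == "low_num_info") {
      value <- if ("num_info" %in% names(edits) && !is.na(edits$num_info[i])) {
        edits$num_info[i]
      } else 3L
      segments$num_info[hit] <- as.integer(value)
    } else {
      stop_input("inject_edge_cases: unknown action '%s'", action)
    }
  }
  segments <- segments[order(segments$sample, segments$chrom, segments$start), ]
  rownames(segments) <- NULL
  segments
}

#' Build synthetic gene sets enriched in planted classes
#'
#' Emits a small GMT-style collection for exercising the enrichment stage:
#' one set per planted class present in the truth (a majority of its
#' members drawn from that class, the rest from null genes) plus random
#' null sets.
#'
#' @param truth truth data.frame from [generate_cohort()].
#' @param set_size members per set.
#' @param enriched_fraction fraction of an enriched set drawn from its class.
#' @param n_random_sets number of additional sets drawn uniformly.
#' @param seed integer seed.
#' @return named list of character vectors (see [write_gmt()]).
#' @export
synthetic_gene_sets <- function(truth, set_size = 25, enriched_fraction = 0.6,
                                n_random_sets = 5, seed = 1L) {
  set.seed(seed)
  sets <- list()
  nulls <- truth$gene_id[truth$class == "null"]
  for (cl in setdiff(unique(truth$class), "null")) {
    members <- truth$gene_id[truth$class == cl]
    n_in <- min(length(members), round_half_up(enriched_fraction * set_size))
    chosen <- c(members[sample.int(length(members), n_in)],
                nulls[sample.int(length(nulls), min(length(nulls), set_size - n_in))])
    attr(chosen, "description") <- paste0("enriched_", cl)
    sets[[paste0("set_", cl)]] <- chosen
  }
  for (j in seq_len(n_random_sets)) {
    chosen <- truth$gene_id[sample.int(nrow(truth), min(set_size, nrow(truth)))]
    attr(chosen, "description") <- "random"
    sets[[sprintf("set_random_%02d", j)]] <- chosen
  }
  sets
}

#' Write all cohort artifacts to a directory
#'
#' Writes the on-disk inputs the pipeline consumes: `segments.seg`
#' (1-based inclusive SEG), `genes.bed`, `methylation.tsv`,
#' `expression_tumor.tsv`, `expression_normal.tsv`, `sample_groups.tsv`,
#' `truth.tsv` and `gene_sets.gmt`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    segments = file.path(dir, "segments.seg"),
    annotation = file.path(dir, "genes.bed"),
    methylation = file.path(dir, "methylation.tsv"),
    expr_tumor = file.path(dir, "expression_tumor.tsv"),
    expr_normal = file.path(dir, "expression_normal.tsv"),
    sample_groups = file.path(dir, "sample_groups.tsv"),
    truth = file.path(dir, "truth.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt")
  )
  write_segments(cohort$segments, paths[["segments"]])
  write_bed(cohort$annotation, paths[["annotation"]])
  write_matrix(cohort$methylation, paths[["methylation"]])
  write_matrix(cohort$expr_tumor, paths[["expr_tumor"]])
  write_matrix(cohort$expr_normal, paths[["expr_normal"]])
  write_sample_groups(cohort$sample_groups, paths[["sample_groups"]])
  write_tsv(cohort$truth, paths[["truth"]])
  write_gmt(synthetic_gene_sets(cohort$truth, seed = cohort$config$seed),
            paths[["gene_sets"]])
  invisible(paths)
}
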