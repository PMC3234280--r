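#' Threshold configuration for CNV state calls and screens
#'
#' Collects every seg.mean cutoff the analysis depends on. Defaults follow
#' the published ovarian-cohort conventions: a gene is amplified at
#' seg.mean >= 0.50 and deleted at seg.mean < 0.00 (frequency tables), the
#' rank-sum expression screen contrasts samples at seg.mean >= 1.25
#' against samples < -0.50 (the low cutoff capturing at minimum a loss of
#' heterozygosity), segments with fewer than 4 informative markers are
#' discarded, 5% of cells nearest zero are trimmed per sign, and a gene
#' must show the relevant state in at least 20% of tumor samples to enter
#' a screen.
#'
#' @param amp_threshold seg.mean at or above which a gene/sample is
#'   amplified.
#' @param del_threshold seg.mean strictly below which a gene/sample is
#'   deleted.
#' @param high_screen_threshold,low_screen_threshold extreme seg.mean
#'   cutoffs for the rank-sum screen groups (high: `>=`, low: `<`).
#' @param min_num_info minimum informative marker count per segment.
#' @param near_zero_trim fraction of positive (and of negative) cells
#'   nearest zero masked by [trim_near_zero()].
#' @param min_sample_fraction minimum fraction of tumor samples a group or
#'   state must cover.
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(amp_threshold = 0.50,
                             del_threshold = 0.00,
                             high_screen_threshold = 1.25,
                             low_screen_threshold = -0.50,
                             min_num_info = 4L,
                             near_zero_trim = 0.05,
                             min_sample_fraction = 0.20) {
  if (del_threshold >= amp_threshold) {
    stop_input("del_threshold must be below amp_threshold")
  }
  if (near_zero_trim < 0 || near_zero_trim >= 0.5) {
    stop_input("near_zero_trim must lie in [0, 0.5)")
  }
  if (min_sample_fraction <= 0 || min_sample_fraction > 1) {
    stop_input("min_sample_fraction must lie in (0, 1]")
  }
  structure(list(
    amp_threshold = amp_threshold, del_threshold = del_threshold,
    high_screen_threshold = high_screen_threshold,
    low_screen_threshold = low_screen_threshold,
    min_num_info = as.integer(min_num_info),
    near_zero_trim = near_zero_trim,
    min_sample_fraction = min_sample_fraction
  ), class = "threshold_config")
}

as_threshold_config <- function(config) {
  if (inherits(config, "threshold_config")) return(config)
  do.call(threshold_config, as.list(config))
}

#' Assign CBS segments to genes under full-containment rules
#'
#' A gene/sample cell receives the seg.mean of the unique segment that
#' fully contains the gene locus. The cell is missing when the gene is
#' split across two or more segments, only partially covered, uncovered,
#' or when its containing segment has fewer than `min_num_info`
#' informative markers.
#'
#' @param segments segment table (internal 0-based half-open coordinates),
#'   per sample sorted and non-overlapping within a chromosome.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param config a [threshold_config()].
#' @return genes x samples numeric matrix of seg.mean values with `NA`
#'   for excluded cells; attribute `filter_counts` tallies exclusions by
#'   reason (`split`, `partial_or_uncovered`, `low_num_info`).
#' @export
assign_segments_to_genes <- function(segments, annotation, config = threshold_config()) {
  config <- as_threshold_config(config)
  validate_annotation(annotation)
  samples <- unique(segments$sample)
  genes_gr <- GRanges(annotation$chrom,
                      IRanges(annotation$start + 1, annotation$end))
  m <- matrix(NA_real_, nrow(annotation), length(samples),
              dimnames = list(annotation$gene_id, samples))
  counts <- c(split = 0L, partial_or_uncovered = 0L, low_num_info = 0L)
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    check_sorted_disjoint(seg, s)
    seg_gr <- GRanges(seg$chrom, IRanges(seg$start + 1, seg$end))
    n_over <- GenomicRanges::countOverlaps(genes_gr, seg_gr)
    within <- findOverlaps(genes_gr, seg_gr, type = "within")
    value <- rep(NA_real_, nrow(annotation))
    hit_gene <- queryHits(within)
    hit_seg <- subjectHits(within)
    ok <- n_over[hit_gene] == 1L
    contained <- hit_gene[ok]
    seg_of <- hit_seg[ok]
    info_ok <- seg$num_info[seg_of] >= config$min_num_info
    value[contained[info_ok]] <- seg$seg_mean[seg_of[info_ok]]
    counts[["low_num_info"]] <- counts[["low_num_info"]] + sum(!info_ok)
    counts[["split"]] <- counts[["split"]] + sum(n_over >= 2L)
    counts[["partial_or_uncovered"]] <- counts[["partial_or_uncovered"]] +
      sum(n_over <= 1L) - length(contained)
    m[, s] <- value
  }
  attr(m, "filter_counts") <- counts
  attr(m, "modality") <- "cnv"
  m
}

check_sorted_disjoint <- function(seg, sample_id) {
  for (ch in unique(seg$chrom)) {
    x <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(x) < 2) next
    if (is.unsorted(x$start)) {
      stop_input("segments for sample %s chrom %s are not sorted", sample_id, ch)
    }
    if (any(x$start[-1] < x$end[-nrow(x)])) {
      stop_input("segments for sample %s chrom %s overlap", sample_id, ch)
    }
  }
}

#' Mask seg.mean cells nearest zero
#'
#' Pools all strictly positive cells of the matrix and masks the
#' `trim_fraction` with the smallest values; symmetrically masks the
#' negative cells with the smallest absolute values. Zeros and missing
#' cells are untouched. This keeps only copy-number signal away from the
#' noise floor around a diploid seg.mean of 0 (5% per sign retains 90% of
#' the data).
#'
#' @param m genes x samples seg.mean matrix.
#' @param trim_fraction fraction per sign in \[0, 0.5); the number of
#'   masked cells per sign is `ceiling(trim_fraction * n_sign)`.
#' @return the matrix with trimmed cells set to `NA`.
#' @export
trim_near_zero <- function(m, trim_fraction = 0.05) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop_input("trim_fraction must lie in [0, 0.5)")
  }
  if (trim_fraction == 0) return(m)
  pos <- which(!is.na(m) & m > 0)
  neg <- which(!is.na(m) & m < 0)
  if (length(pos) > 0) {
    k <- ceiling(trim_fraction * length(pos))
    m[pos[order(m[pos])][seq_len(k)]] <- NA_real_
  }
  if (length(neg) > 0) {
    k <- ceiling(trim_fraction * length(neg))
    m[neg[order(-m[neg])][seq_len(k)]] <- NA_real_
  }
  m
}

#' Classify seg.mean values into CNV states
#'
#' `amplified` at or above the amplification threshold, `deleted` strictly
#' below the deletion threshold, `neutral` otherwise; missing values stay
#' missing. With the defaults a seg.mean of exactly 0.00 is neutral.
#'
#' @param seg_mean numeric vector or matrix of seg.mean values.
#' @param config a [threshold_config()].
#' @return character vector/matrix of states in
#'   `{"amplified", "neutral", "deleted", NA}`.
#' @export
classify_cnv_state <- function(seg_mean, config = threshold_config()) {
  config <- as_threshold_config(config)
  state <- ifelse(is.na(seg_mean), NA_character_,
           ifelse(seg_mean >= config$amp_threshold, "amplified",
           ifelse(seg_mean < config$del_threshold, "deleted", "neutral")))
  if (is.matrix(seg_mean)) {
    state <- matrix(state, nrow(seg_mean), dimnames = dimnames(seg_mean))
  }
  state
}

#' Per-gene CNV state frequencies
#'
#' Fraction of non-missing samples in which each gene is amplified,
#' neutral or deleted; rows with no observed state are all-`NA`.
#'
#' @param states genes x samples state matrix from [classify_cnv_state()].
#' @return data.frame `gene_id`, `n_observed`, `amplified`, `neutral`,
#'   `deleted` (fractions summing to 1 where observed).
#' @export
alteration_frequency <- function(states) {
  n_obs <- rowSums(!is.na(states))
  frac <- function(st) ifelse(n_obs > 0, rowSums(states == st, na.rm = TRUE) / n_obs,
                              NA_real_)
  data.frame(
    gene_id = rownames(states),
    n_observed = as.integer(n_obs),
    amplified = frac("amplified"),
    neutral = frac("neutral"),
    deleted = frac("deleted"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Calibrate a platform-specific deletion threshold
#'
#' Given two seg.mean matrices over shared samples, finds the grid
#' threshold on platform B that best reproduces the reference deleted
#' calls made on platform A: the objective is sensitivity to
#' reference-deleted cells minus the false-positive rate among
#' reference-amplified/neutral cells, the single-scalar reading of
#' "capture a maximum percentage of deleted genes while maintaining a
#' minimum false positive percentage". Ties prefer the threshold nearest
#' zero.
#'
#' @param matrix_a,matrix_b genes x samples seg.mean matrices for the
#'   reference and target platforms.
#' @param shared_samples sample ids present on both platforms.
#' @param reference_config [threshold_config()] whose `del_threshold`
#'   defines the reference deleted state on platform A.
#' @param grid candidate thresholds for platform B.
#' @return list with `threshold`, `sensitivity`, `fpr` at the optimum and
#'   the full `grid` evaluation data.frame.
#' @export
calibrate_platform_threshold <- function(matrix_a, matrix_b, shared_samples,
                                         reference_config = threshold_config(),
                                         grid = seq(-1, 0, by = 0.05)) {
  reference_config <- as_threshold_config(reference_config)
  if (length(shared_samples) == 0) stop_input("no shared samples to calibrate on")
  if (length(grid) == 0) stop_input("empty calibration grid")
  miss <- setdiff(shared_samples, intersect(colnames(matrix_a), colnames(matrix_b)))
  if (length(miss) > 0) {
    stop_input("shared sample '%s' absent from one platform", miss[1])
  }
  genes <- intersect(rownames(matrix_a), rownames(matrix_b))
  if (length(genes) == 0) stop_input("no shared genes to calibrate on")
  a <- matrix_a[genes, shared_samples, drop = FALSE]
  b <- matrix_b[genes, shared_samples, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  ref_del <- a < reference_config$del_threshold
  n_del <- sum(ref_del & ok)
  n_not <- sum(!ref_del & ok)
  if (n_del == 0 || n_not == 0) {
    stop_input("reference platform yields no %s cells; cannot calibrate",
               if (n_del == 0) "deleted" else "non-deleted")
  }
  eval_grid <- data.frame(threshold = grid)
  eval_grid$sensitivity <- vapply(grid, function(t)
    sum(b < t & ref_del & ok) / n_del, numeric(1))
  eval_grid$fpr <- vapply(grid, function(t)
    sum(b < t & !ref_del & ok) / n_not, numeric(1))
  eval_grid$objective <- eval_grid$sensitivity - eval_grid$fpr
  ord <- order(-eval_grid$objective, abs(eval_grid$threshold), eval_grid$threshold)
  best <- ord[1]
  list(threshold = eval_grid$threshold[best],
       sensitivity = eval_grid$sensitivity[best],
       fpr = eval_grid$fpr[best],
       grid = eval_grid)
}

#' Extract copy-number breakpoints from segment tables
#'
#' A breakpoint sits at the boundary of two adjacent segments whose CNV
#' states differ. Its direction is the state of the downstream segment
#' when that segment is non-neutral (`gain` for amplified, `loss` for
#' deleted); when the transition returns to neutral, the direction is
#' inherited from the upstream non-neutral segment.
#'
#' @param segments segment table (internal coordinates), per sample/chrom
#'   sorted.
#' @param config a [threshold_config()] defining the states.
#' @return data.frame `sample`, `chrom`, `position`, `direction`.
#' @export
extract_breakpoints <- function(segments, config = threshold_config()) {
  config <- as_threshold_config(config)
  out <- list()
  k <- 0
  for (s in unique(segments$sample)) {
    seg_s <- segments[segments$sample == s, , drop = FALSE]
    for (ch in unique(seg_s$chrom)) {
      x <- seg_s[seg_s$chrom == ch, , drop = FALSE]
      x <- x[order(x$start), , drop = FALSE]
      if (nrow(x) < 2) next
      st <- classify_cnv_state(x$seg_mean, config)
      for (i in seq_len(nrow(x) - 1)) {
        if (st[i] == st[i + 1]) next
        dir_state <- if (st[i + 1] != "neutral") st[i + 1] else st[i]
        k <- k + 1
        out[[k]] <- data.frame(
          sample = s, chrom = ch, position = x$end[i],
          direction = if (dir_state == "amplified") "gain" else "loss",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      position = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
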