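#' Mean expression within seg.mean bins
#'
#' Pools all gene/sample pairs with both a seg.mean and an expression
#' value and averages expression within consecutive seg.mean bins. Under
#' gene-dosage coupling the bin means rise from deletion to amplification.
#'
#' @param expr,cnv genes x samples matrices sharing gene and sample ids.
#' @param bin_edges increasing numeric vector of bin boundaries covering
#'   the observed seg.mean range; bins are left-closed, the last bin is
#'   closed on both sides.
#' @return data.frame `bin_low`, `bin_high`, `n_pairs`, `mean_expr`
#'   (`NA` for empty bins).
#' @export
expression_by_cnv_bins <- function(expr, cnv, bin_edges) {
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop_input("bin_edges must be strictly increasing")
  }
  genes <- intersect(rownames(expr), rownames(cnv))
  samples <- intersect(colnames(expr), colnames(cnv))
  e <- expr[genes, samples, drop = FALSE]
  c_ <- cnv[genes, samples, drop = FALSE]
  ok <- !is.na(e) & !is.na(c_)
  x <- c_[ok]
  y <- e[ok]
  if (any(x < bin_edges[1] | x > bin_edges[length(bin_edges)])) {
    stop_input("bin_edges do not cover the observed seg.mean range [%g, %g]",
               min(x), max(x))
  }
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1
  data.frame(
    bin_low = bin_edges[-length(bin_edges)],
    bin_high = bin_edges[-1],
    n_pairs = tabulate(bin, n_bins),
    mean_expr = vapply(seq_len(n_bins), function(b) {
      v <- y[bin == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Maximum cumulative-distribution gap between two expression sets
#'
#' The supremum over expression thresholds of the difference between the
#' empirical CDFs of two sets of expression values (typically the
#' deleted-state and amplified-state gene/sample pairs) -- the two-sample
#' Kolmogorov-Smirnov statistic.
#'
#' @param expr_low,expr_high numeric vectors of expression values; both
#'   must be non-empty.
#' @return the maximum absolute CDF difference in \[0, 1\].
#' @export
cnv_expression_cdf_gap <- function(expr_low, expr_high) {
  expr_low <- expr_low[!is.na(expr_low)]
  expr_high <- expr_high[!is.na(expr_high)]
  if (length(expr_low) == 0 || length(expr_high) == 0) {
    stop_input("both expression sets must be non-empty")
  }
  at <- sort(unique(c(expr_low, expr_high)))
  max(abs(ecdf(expr_low)(at) - ecdf(expr_high)(at)))
}

#' Per-gene Pearson correlation screen between two modalities
#'
#' For every shared gene, the product-moment correlation across shared
#' samples with complete pairs, a two-sided p-value from the
#' t-transform with n-2 degrees of freedom, and BH q-values over the
#' tested genes. For the methylation-expression screen set
#' `flip_x = TRUE`: the correlation of (-x, y) is reported so that
#' repressive genes (high methylation, low expression) score positive.
#'
#' @param x_matrix,y_matrix genes x samples matrices (x: cnv or
#'   methylation; y: expression).
#' @param min_pairs minimum complete observations per gene.
#' @param flip_x report the correlation of `-x` with `y`.
#' @param test label recorded in the output.
#' @return data.frame `gene_id`, `test`, `n`, `r`, `statistic`, `p_value`,
#'   `q_value`, `flipped`, `skip_reason`.
#' @export
per_gene_correlation <- function(x_matrix, y_matrix, min_pairs = 5,
                                 flip_x = FALSE,
                                 test = if (flip_x) "pearson_meth_expr" else "pearson_cnv_expr") {
  genes <- intersect(rownames(x_matrix), rownames(y_matrix))
  samples <- intersect(colnames(x_matrix), colnames(y_matrix))
  if (length(samples) < 3) stop_input("need at least 3 shared samples")
  res <- data.frame(
    gene_id = genes, test = test, n = 0L, r = NA_real_,
    statistic = NA_real_, p_value = NA_real_, q_value = NA_real_,
    flipped = flip_x, skip_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(genes)) {
    x <- x_matrix[genes[i], samples]
    y <- y_matrix[genes[i], samples]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    res$n[i] <- n
    if (n < min_pairs) {
      res$skip_reason[i] <- "too_few_pairs"
      next
    }
    x <- x[ok]
    y <- y[ok]
    if (var(x) == 0 || var(y) == 0) {
      res$skip_reason[i] <- "zero_variance"
      next
    }
    r <- cor(if (flip_x) -x else x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    res$r[i] <- r
    res$statistic[i] <- tstat
    res$p_value[i] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  res$q_value <- bh_adjust(res$p_value)
  res
}

# Two-sided two-sample rank-sum p-value; exact when both groups are small
# and the pooled values are tie-free, otherwise the tie-corrected normal
# approximation with continuity correction.
rank_sum_p <- function(low, high, exact_max = 8) {
  ties <- anyDuplicated(c(low, high)) > 0
  use_exact <- !ties && length(low) <= exact_max && length(high) <= exact_max
  res <- suppressWarnings(
    wilcox.test(low, high, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  list(p = res$p.value, statistic = unname(res$statistic), exact = use_exact)
}

#' Rank-sum screen of expression between extreme-CNV sample groups
#'
#' For each gene, tumor samples are split into a low-CNV group
#' (seg.mean < `low_screen_threshold`) and a high-CNV group
#' (seg.mean >= `high_screen_threshold`). Genes whose groups each cover at
#' least `min_sample_fraction` of the tumor samples are tested with a
#' two-sided Mann-Whitney rank-sum test on expression (exact when both
#' groups have at most 8 samples and no ties; tie-corrected normal
#' approximation with continuity correction otherwise), and BH q-values
#' are computed over the tested genes. Untested genes carry the skip
#' reason.
#'
#' @param expr,cnv genes x tumor-samples matrices sharing ids.
#' @param config a [threshold_config()].
#' @return data.frame `gene_id`, `test`, `n_low`, `n_high`, `statistic`,
#'   `p_value`, `q_value`, `skip_reason`; attribute `filter_counts`.
#' @export
wilcoxon_cnv_screen <- function(expr, cnv, config = threshold_config()) {
  config <- as_threshold_config(config)
  genes <- intersect(rownames(expr), rownames(cnv))
  samples <- intersect(colnames(expr), colnames(cnv))
  n_tumor <- length(samples)
  min_n <- config$min_sample_fraction * n_tumor
  res <- data.frame(
    gene_id = genes, test = "wilcoxon_cnv", n_low = 0L, n_high = 0L,
    statistic = NA_real_, p_value = NA_real_, q_value = NA_real_,
    skip_reason = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_along(genes)) {
    x <- cnv[genes[i], samples]
    y <- expr[genes[i], samples]
    ok <- !is.na(x) & !is.na(y)
    low <- y[ok & x < config$low_screen_threshold]
    high <- y[ok & x >= config$high_screen_threshold]
    res$n_low[i] <- length(low)
    res$n_high[i] <- length(high)
    small <- c(if (length(low) < min_n) "low_group_too_small",
               if (length(high) < min_n) "high_group_too_small")
    if (length(small) > 0) {
      res$skip_reason[i] <- paste(small, collapse = ";")
      next
    }
    rs <- rank_sum_p(low, high)
    res$statistic[i] <- rs$statistic
    res$p_value[i] <- rs$p
  }
  res$q_value <- bh_adjust(res$p_value)
  attr(res, "filter_counts") <- c(
    tested = sum(!is.na(res$p_value)),
    skipped = sum(is.na(res$p_value))
  )
  res
}

#' Sweep the high-CNV screen threshold
#'
#' Re-runs [wilcoxon_cnv_screen()] for each candidate high threshold while
#' the low threshold stays fixed, counting tested genes and genes
#' significant at the FDR level. Raising the high threshold shrinks the
#' high group, so the tested-gene count is non-increasing along the grid.
#'
#' @param expr,cnv genes x tumor-samples matrices.
#' @param high_grid candidate high-CNV thresholds.
#' @param config a [threshold_config()] supplying the fixed low threshold.
#' @param fdr_level q-value cutoff for the significant count.
#' @return data.frame `high_threshold`, `n_tested`, `n_significant`.
#' @export
threshold_sweep <- function(expr, cnv, high_grid,
                            config = threshold_config(), fdr_level = 0.05) {
  if (length(high_grid) == 0) stop_input("high_grid must be non-empty")
  config <- as_threshold_config(config)
  rows <- lapply(high_grid, function(t) {
    cfg <- config
    cfg$high_screen_threshold <- t
    scr <- wilcoxon_cnv_screen(expr, cnv, cfg)
    data.frame(high_threshold = t,
               n_tested = sum(!is.na(scr$p_value)),
               n_significant = sum(scr$q_value < fdr_level, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Filter genes whose gated tumor expression deviates from normals
#'
#' A gene passes the CNV gate when at least `min_sample_fraction` of the
#' tumor samples show |seg.mean| above `deviation_cnv_threshold`. Among
#' gated samples, the gene is retained as deviant when the tumor mean
#' expression differs from the normal mean by more than one tumor
#' standard deviation.
#'
#' @param expr,cnv genes x tumor-samples matrices.
#' @param normal_expr genes x normal-samples expression matrix.
#' @param config a [threshold_config()].
#' @param deviation_cnv_threshold absolute seg.mean defining an altered
#'   sample.
#' @return data.frame `gene_id`, `n_gated`, `tumor_mean`, `normal_mean`,
#'   `tumor_sd`, `gate_passed`, `retained`.
#' @export
normal_deviation_filter <- function(expr, cnv, normal_expr,
                                    config = threshold_config(),
                                    deviation_cnv_threshold = 0.50) {
  config <- as_threshold_config(config)
  genes <- Reduce(intersect, list(rownames(expr), rownames(cnv), rownames(normal_expr)))
  samples <- intersect(colnames(expr), colnames(cnv))
  if (ncol(normal_expr) < 1) stop_input("need at least one normal sample")
  min_n <- config$min_sample_fraction * length(samples)
  res <- data.frame(
    gene_id = genes, n_gated = 0L, tumor_mean = NA_real_,
    normal_mean = NA_real_, tumor_sd = NA_real_,
    gate_passed = FALSE, retained = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_along(genes)) {
    x <- cnv[genes[i], samples]
    gated <- which(!is.na(x) & abs(x) > deviation_cnv_threshold)
    res$n_gated[i] <- length(gated)
    if (length(gated) < min_n || length(gated) < 2) next
    y <- expr[genes[i], samples][gated]
    y <- y[!is.na(y)]
    if (length(y) < 2) next
    nm <- mean(normal_expr[genes[i], ], na.rm = TRUE)
    res$gate_passed[i] <- TRUE
    res$tumor_mean[i] <- mean(y)
    res$normal_mean[i] <- nm
    res$tumor_sd[i] <- sd(y)
    res$retained[i] <- abs(mean(y) - nm) > sd(y)
  }
  res
}
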