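#' Select genes with extreme copy-number variation
#'
#' A gene enters the amplified class when at least `min_sample_fraction`
#' of the tumor samples carry seg.mean at or above the amplification
#' threshold, and the deleted class when that fraction of samples falls
#' strictly below the low screen threshold (the platform-appropriate
#' extreme-deletion cutoff, -0.50 by default, capturing at minimum a
#' single-copy loss). A gene may belong to both classes through different
#' sample subsets.
#'
#' @param cnv genes x tumor-samples seg.mean matrix.
#' @param config a [threshold_config()].
#' @return list with character vectors `amplified` and `deleted`.
#' @export
select_extreme_cnv_genes <- function(cnv, config = threshold_config()) {
  config <- as_threshold_config(config)
  n_tumor <- ncol(cnv)
  min_n <- config$min_sample_fraction * n_tumor
  n_amp <- rowSums(cnv >= config$amp_threshold, na.rm = TRUE)
  n_del <- rowSums(cnv < config$low_screen_threshold, na.rm = TRUE)
  list(amplified = rownames(cnv)[n_amp >= min_n],
       deleted = rownames(cnv)[n_del >= min_n])
}

#' Tumor-to-normal expression ratio per gene
#'
#' The ratio of mean tumor expression to mean normal expression on the
#' linear scale (log2 input is unlogged before averaging, matching the
#' ratio-of-signals semantics). When a gene has no native normal values,
#' the normal mean is estimated from a donor normal matrix by bootstrap:
#' the average, over `bootstrap_reps` resamples with replacement of size
#' equal to the donor count, of the resample means. Deterministic given
#' `seed`.
#'
#' @param expr_tumor genes x tumor-samples matrix.
#' @param expr_normal genes x normal-samples matrix (may be `NULL` or
#'   have all-`NA` rows).
#' @param donor_normal optional donor matrix used when native normals are
#'   absent for a gene.
#' @param bootstrap_reps number of bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param log2_input are the matrices on the log2 scale?
#' @return data.frame `gene_id`, `tumor_mean`, `normal_mean`, `ratio`,
#'   `normal_source` in `{"native", "bootstrap", "absent"}`; genes with no
#'   normal information anywhere have `NA` ratios.
#' @export
tumor_normal_expression_ratio <- function(expr_tumor, expr_normal = NULL,
                                          donor_normal = NULL,
                                          bootstrap_reps = 50, seed = 1L,
                                          log2_input = TRUE) {
  unlog <- function(x) if (log2_input) 2^x else x
  set.seed(seed)
  genes <- rownames(expr_tumor)
  res <- data.frame(
    gene_id = genes, tumor_mean = NA_real_, normal_mean = NA_real_,
    ratio = NA_real_, normal_source = "absent", stringsAsFactors = FALSE
  )
  for (i in seq_along(genes)) {
    tv <- unlog(expr_tumor[i, ])
    tv <- tv[!is.na(tv)]
    if (length(tv) == 0) next
    res$tumor_mean[i] <- mean(tv)
    nv <- if (!is.null(expr_normal) && genes[i] %in% rownames(expr_normal)) {
      v <- unlog(expr_normal[genes[i], ])
      v[!is.na(v)]
    } else numeric(0)
    if (length(nv) > 0) {
      res$normal_mean[i] <- mean(nv)
      res$normal_source[i] <- "native"
    } else if (!is.null(donor_normal) && genes[i] %in% rownames(donor_normal)) {
      dv <- unlog(donor_normal[genes[i], ])
      dv <- dv[!is.na(dv)]
      if (length(dv) == 0) next
      reps <- vapply(seq_len(bootstrap_reps), function(r)
        mean(dv[sample.int(length(dv), length(dv), replace = TRUE)]),
        numeric(1))
      res$normal_mean[i] <- mean(reps)
      res$normal_source[i] <- "bootstrap"
    } else {
      next
    }
    res$ratio[i] <- res$tumor_mean[i] / res$normal_mean[i]
  }
  res
}

#' Quantile cutpoints for expression ratios and methylation
#'
#' Computes the classification cutpoints at the `q` and `1 - q` empirical
#' quantiles (linear interpolation) of the entire ratio and methylation
#' distributions, i.e. the top/bottom 25% rule at the default.
#'
#' @param ratios per-gene tumor:normal expression ratios.
#' @param meth_values per-gene methylation levels.
#' @param q lower quantile (default 0.25).
#' @return list `ratio_low`, `ratio_high`, `meth_low`, `meth_high`.
#' @export
compute_quantile_thresholds <- function(ratios, meth_values, q = 0.25) {
  ratios <- ratios[!is.na(ratios)]
  meth_values <- meth_values[!is.na(meth_values)]
  if (length(ratios) < 4 || length(meth_values) < 4) {
    stop_input("need at least 4 observed ratios and methylation values")
  }
  if (q <= 0 || q > 0.5) stop_input("q must lie in (0, 0.5]")
  list(
    ratio_low = unname(quantile(ratios, q)),
    ratio_high = unname(quantile(ratios, 1 - q)),
    meth_low = unname(quantile(meth_values, q)),
    meth_high = unname(quantile(meth_values, 1 - q))
  )
}

#' Classify extreme-CNV genes into feature quadrants
#'
#' Joint rule over CNV class, tumor:normal expression ratio and
#' methylation at the class-defining samples:
#' \describe{
#'   \item{oncogene_like}{amplified, ratio >= `ratio_high`,
#'     methylation <= `meth_low` (overexpressed, hypomethylated).}
#'   \item{ts_like}{deleted, ratio <= `ratio_low`, methylation >=
#'     `meth_high` (suppressed, hypermethylated).}
#'   \item{amplified_suppressed}{amplified yet suppressed and
#'     hypermethylated (epigenetic silencing despite copy gain).}
#'   \item{deleted_expressed}{deleted yet expressed and hypomethylated.}
#' }
#' Genes meeting neither pair of conditions are `none`. The reported
#' methylation is the tumor mean over the samples in the CNV class (the
#' amplified samples for the amplified class, deleted samples for the
#' deleted class).
#'
#' @param cnv genes x tumor-samples seg.mean matrix.
#' @param meth genes x samples methylation matrix (tumor columns used).
#' @param ratios data.frame from [tumor_normal_expression_ratio()].
#' @param thresholds list from [compute_quantile_thresholds()].
#' @param config a [threshold_config()].
#' @param extreme optional precomputed [select_extreme_cnv_genes()] sets.
#' @return data.frame with one row per (gene, CNV class) membership:
#'   `gene_id`, `cnv_class`, `n_class_samples`, `meth_mean`, `expr_ratio`,
#'   `feature_class`.
#' @export
classify_features <- function(cnv, meth, ratios, thresholds,
                              config = threshold_config(), extreme = NULL) {
  config <- as_threshold_config(config)
  if (is.null(extreme)) extreme <- select_extreme_cnv_genes(cnv, config)
  tumor_cols <- intersect(colnames(meth), colnames(cnv))
  ratio_of <- setNames(ratios$ratio, ratios$gene_id)
  rows <- list()
  k <- 0
  for (cl in c("amplified", "deleted")) {
    for (g in extreme[[cl]]) {
      x <- cnv[g, tumor_cols]
      in_class <- if (cl == "amplified") {
        !is.na(x) & x >= config$amp_threshold
      } else {
        !is.na(x) & x < config$low_screen_threshold
      }
      mvals <- meth[g, tumor_cols][in_class]
      m <- if (all(is.na(mvals))) NA_real_ else mean(mvals, na.rm = TRUE)
      r <- unname(ratio_of[g])
      if (length(r) == 0) r <- NA_real_
      feature <- "none"
      if (!is.na(m) && !is.na(r)) {
        hi_r <- r >= thresholds$ratio_high
        lo_r <- r <= thresholds$ratio_low
        hi_m <- m >= thresholds$meth_high
        lo_m <- m <= thresholds$meth_low
        if (cl == "amplified" && hi_r && lo_m) feature <- "oncogene_like"
        else if (cl == "deleted" && lo_r && hi_m) feature <- "ts_like"
        else if (cl == "amplified" && lo_r && hi_m) feature <- "amplified_suppressed"
        else if (cl == "deleted" && hi_r && lo_m) feature <- "deleted_expressed"
      }
      k <- k + 1
      rows[[k]] <- data.frame(
        gene_id = g, cnv_class = cl, n_class_samples = sum(in_class),
        meth_mean = m, expr_ratio = r, feature_class = feature,
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0) {
    return(data.frame(gene_id = character(), cnv_class = character(),
                      n_class_samples = integer(), meth_mean = numeric(),
                      expr_ratio = numeric(), feature_class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two-sample Hotelling T^2 test on multivariate observations, in the
# unequal-covariance (Behrens-Fisher) form T^2 = d' (S1/n1 + S2/n2)^-1 d
# with Nel-van der Merwe approximate degrees of freedom -- the
# multivariate analog of the Welch t-test used for the univariate
# screens (groups here are strongly heteroscedastic: tumors carry the
# alteration mixture, normals do not). The statistic falls back to the
# Moore-Penrose pseudoinverse when the combined covariance is singular
# (e.g. perfectly correlated modalities), in which case the p-value is
# reported missing.
hotelling_t2 <- function(x, y) {
  p <- ncol(x)
  n1 <- nrow(x)
  n2 <- nrow(y)
  if (n1 < 2 || n2 < 2) {
    return(list(t2 = NA_real_, f = NA_real_, p_value = NA_real_))
  }
  d <- colMeans(x) - colMeans(y)
  w1 <- stats::cov(x) / n1
  w2 <- stats::cov(y) / n2
  se <- w1 + w2
  rank_se <- qr(se)$rank
  t2 <- as.numeric(t(d) %*% MASS::ginv(se) %*% d)
  if (rank_se < p) {
    return(list(t2 = t2, f = NA_real_, p_value = NA_real_))
  }
  tr <- function(m) sum(diag(m))
  denom <- (tr(w1 %*% w1) + tr(w1)^2) / (n1 - 1) +
    (tr(w2 %*% w2) + tr(w2)^2) / (n2 - 1)
  if (denom <= 0) {
    nu <- n1 + n2 - 2            # degenerate zero-variance input
  } else {
    nu <- (tr(se %*% se) + tr(se)^2) / denom
  }
  if (nu <= p - 1) {
    return(list(t2 = t2, f = NA_real_, p_value = NA_real_))
  }
  fstat <- (nu - p + 1) / (nu * p) * t2
  list(t2 = t2, f = fstat,
       p_value = pf(fstat, p, nu - p + 1, lower.tail = FALSE))
}

#' Per-gene significance of tumor vs normal methylation and expression
#'
#' For every gene with both modalities in at least 2 tumor and 2 normal
#' samples: the Euclidean distances between the tumor-mean and
#' normal-mean points per modality and jointly (reported as effect
#' sizes), two-sided Welch t-tests per modality, a two-sample Hotelling
#' T-squared test on the joint per-sample (methylation, expression)
#' pairs, and BH q-values over the genes' multivariate p-values. A
#' singular pooled covariance leaves the multivariate p missing while the
#' univariate results stand.
#'
#' @param meth genes x samples methylation matrix (tumors and normals).
#' @param expr genes x samples expression matrix (tumors and normals; pass
#'   `cbind(expr_tumor, expr_normal)`).
#' @param groups data.frame (`sample_id`, `group`).
#' @return data.frame `gene_id`, `euclid_meth`, `euclid_expr`,
#'   `euclid_joint`, `p_uni_meth`, `p_uni_expr`, `p_multi`, `q_multi`.
#' @export
normal_vs_tumor_significance <- function(meth, expr, groups) {
  genes <- intersect(rownames(meth), rownames(expr))
  tum <- intersect(intersect(colnames(meth), colnames(expr)),
                   groups$sample_id[groups$group == "tumor"])
  nor <- intersect(intersect(colnames(meth), colnames(expr)),
                   groups$sample_id[groups$group == "normal"])
  if (length(tum) < 2 || length(nor) < 2) {
    stop_input("need >= 2 tumor and >= 2 normal samples with both modalities")
  }
  res <- data.frame(
    gene_id = genes, euclid_meth = NA_real_, euclid_expr = NA_real_,
    euclid_joint = NA_real_, p_uni_meth = NA_real_, p_uni_expr = NA_real_,
    p_multi = NA_real_, q_multi = NA_real_, stringsAsFactors = FALSE
  )
  welch_p <- function(a, b) {
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  }
  for (i in seq_along(genes)) {
    g <- genes[i]
    mt <- meth[g, tum]; mn <- meth[g, nor]
    et <- expr[g, tum]; en <- expr[g, nor]
    ok_t <- !is.na(mt) & !is.na(et)
    ok_n <- !is.na(mn) & !is.na(en)
    if (sum(ok_t) < 2 || sum(ok_n) < 2) next
    dm <- mean(mt[ok_t]) - mean(mn[ok_n])
    de <- mean(et[ok_t]) - mean(en[ok_n])
    res$euclid_meth[i] <- abs(dm)
    res$euclid_expr[i] <- abs(de)
    res$euclid_joint[i] <- sqrt(dm^2 + de^2)
    res$p_uni_meth[i] <- welch_p(mt[ok_t], mn[ok_n])
    res$p_uni_expr[i] <- welch_p(et[ok_t], en[ok_n])
    ht <- hotelling_t2(cbind(mt[ok_t], et[ok_t]), cbind(mn[ok_n], en[ok_n]))
    res$p_multi[i] <- ht$p_value
  }
  res$q_multi <- bh_adjust(res$p_multi)
  res
}

#' Percentile-rank significant calls
#'
#' Among genes passing the FDR cutoff on the multivariate q-value, ranks
#' ascending by q (ties broken by gene id) and maps rank to a percentile:
#' `100 * (1 - (rank - 1) / (n - 1))`, so the most significant gene
#' scores 100 and the weakest passing gene 0; a single passing gene
#' scores 100. Non-passing genes get no rank.
#'
#' @param calls data.frame with `gene_id` and `q_multi` (e.g. from
#'   [normal_vs_tumor_significance()]).
#' @param fdr_level q-value cutoff.
#' @return the input with a `percentile_rank` column.
#' @export
percentile_rank_calls <- function(calls, fdr_level = 0.05) {
  calls$percentile_rank <- NA_real_
  pass <- which(!is.na(calls$q_multi) & calls$q_multi < fdr_level)
  n <- length(pass)
  if (n == 1) {
    calls$percentile_rank[pass] <- 100
  } else if (n > 1) {
    ord <- pass[order(calls$q_multi[pass], calls$gene_id[pass])]
    calls$percentile_rank[ord] <- 100 * (1 - (seq_len(n) - 1) / (n - 1))
  }
  calls
}
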