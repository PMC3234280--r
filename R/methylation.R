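#' Quantile-normalize a matrix across samples
#'
#' Forces every sample (column) onto a common distribution: after
#' normalization each column's sorted values equal the row-wise mean of
#' the sorted input columns, while within-column rank order is preserved.
#' Tied input values receive the mean of the reference values at their
#' tied ranks; missing cells are excluded per column and reinserted as
#' missing (columns with unequal missingness are mapped by quantile
#' interpolation).
#'
#' @param m numeric matrix, at least 2 columns, each with at least 2
#'   observed values.
#' @return the normalized matrix with dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || ncol(m) < 2) {
    stop_input("quantile_normalize needs a matrix with >= 2 columns")
  }
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2)) {
    stop_input("column '%s' has fewer than 2 observed values",
               colnames(m)[which(n_obs < 2)[1]] %||% which(n_obs < 2)[1])
  }
  n <- nrow(m)
  # reference distribution: row-wise mean of the sorted columns; columns
  # with missing cells contribute by interpolation onto n quantiles
  sorted <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[, j])
    if (length(v) == n) v
    else stats::approx(seq_along(v), v,
                       xout = seq(1, length(v), length.out = n))$y
  }, numeric(n))
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- which(!is.na(m[, j]))
    nv <- length(obs)
    ref_j <- if (nv == n) ref
             else stats::approx(seq_len(n), ref,
                                xout = seq(1, n, length.out = nv))$y
    x <- m[obs, j]
    o <- order(x)
    res <- numeric(nv)
    i <- 1
    while (i <= nv) {
      k <- i
      while (k < nv && x[o[k + 1]] == x[o[i]]) k <- k + 1
      res[o[i:k]] <- mean(ref_j[i:k])   # ties: mean of reference at tied ranks
      i <- k + 1
    }
    out[obs, j] <- res
  }
  out
}

#' Assign probe-level methylation to genes
#'
#' Two platform dialects are supported.
#'
#' `moma_ratio` (McrBc-vs-mock GeoMeanRatio tiling arrays): probes belong
#' to restriction fragments; the fragment score per sample is the maximum
#' probe score, each fragment is attributed to the gene whose TSS-proximal
#' end lies nearest the fragment midpoint, and the gene score per sample
#' is the maximum over its fragments.
#'
#' `beta` (Infinium-style per-gene beta values): probes carry a `gene_id`
#' and the gene score is the mean beta over its probes, reported only for
#' genes measured by 2 or more probes.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`,
#'   `end`, plus `fragment_id` (moma_ratio) or `gene_id` (beta), followed
#'   by one numeric column per sample.
#' @param annotation gene annotation data.frame (used for the
#'   closest-gene rule and to order/complete the output rows).
#' @param dialect `"moma_ratio"` or `"beta"`.
#' @return genes x samples matrix over all annotation genes; genes with
#'   no assigned signal are `NA`.
#' @export
assign_methylation_to_genes <- function(probes, annotation,
                                        dialect = c("moma_ratio", "beta")) {
  dialect <- match.arg(dialect)
  validate_annotation(annotation)
  meta_cols <- c("probe_id", "chrom", "start", "end",
                 if (dialect == "moma_ratio") "fragment_id" else "gene_id")
  missing_cols <- setdiff(meta_cols, names(probes))
  if (length(missing_cols) > 0) {
    stop_input("probe table is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(probes), c("probe_id", "chrom", "start", "end",
                                          "fragment_id", "gene_id"))
  if (length(sample_cols) == 0) stop_input("probe table has no sample columns")
  scores <- as.matrix(probes[sample_cols])
  out <- matrix(NA_real_, nrow(annotation), length(sample_cols),
                dimnames = list(annotation$gene_id, sample_cols))

  if (dialect == "beta") {
    for (g in unique(probes$gene_id)) {
      rows <- which(probes$gene_id == g)
      if (length(rows) < 2 || !g %in% annotation$gene_id) next
      out[g, ] <- colMeans(scores[rows, , drop = FALSE], na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    return(out)
  }

  tss <- ifelse(annotation$strand == "-", annotation$end, annotation$start)
  frag_ids <- unique(probes$fragment_id)
  for (f in frag_ids) {
    rows <- which(probes$fragment_id == f)
    sub <- scores[rows, , drop = FALSE]
    if (all(is.na(sub))) {
      warning(sprintf("fragment '%s' has no probe signal; skipped", f))
      next
    }
    frag_val <- apply(sub, 2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    mid <- (min(probes$start[rows]) + max(probes$end[rows])) / 2
    same_chrom <- which(annotation$chrom == probes$chrom[rows[1]])
    if (length(same_chrom) == 0) next
    d_tss <- abs(mid - tss[same_chrom])
    # gap to the gene body (0 when the midpoint falls inside the gene)
    d_body <- pmax(annotation$start[same_chrom] - mid,
                   mid - annotation$end[same_chrom], 0)
    ord <- order(d_tss, d_body, annotation$gene_id[same_chrom])
    g <- same_chrom[ord[1]]
    cur <- out[g, ]
    out[g, ] <- pmax(cur, frag_val, na.rm = TRUE)
    out[g, is.na(cur) & is.na(frag_val)] <- NA_real_
  }
  out
}

#' Rank genes by tumor-to-normal methylation ratio
#'
#' Per gene, the ratio of mean tumor methylation to mean normal
#' methylation. Genes in the top `extreme_fraction` of the ratio
#' distribution are flagged hypermethylated, the bottom `extreme_fraction`
#' hypomethylated (e.g. a ratio of 1.56 reads as a 56% methylation
#' increase in tumors).
#'
#' @param meth genes x samples methylation matrix covering tumor and
#'   normal samples.
#' @param groups data.frame (`sample_id`, `group`) classing the columns.
#' @param extreme_fraction fraction flagged at each extreme; the flag
#'   count is `round(extreme_fraction * n_genes)` (half up).
#' @return data.frame `gene_id`, `tumor_mean`, `normal_mean`, `ratio`,
#'   `flag` in `{"hypermethylated", "hypomethylated", "none"}`, sorted by
#'   decreasing ratio. Genes with a zero normal mean are skipped with a
#'   warning.
#' @export
methylation_tumor_normal_ranking <- function(meth, groups, extreme_fraction = 0.10) {
  tum <- intersect(colnames(meth), groups$sample_id[groups$group == "tumor"])
  nor <- intersect(colnames(meth), groups$sample_id[groups$group == "normal"])
  if (length(nor) == 0) stop_input("no normal samples in methylation matrix")
  if (extreme_fraction < 0 || extreme_fraction > 0.5) {
    stop_input("extreme_fraction must lie in [0, 0.5]")
  }
  tumor_mean <- rowMeans(meth[, tum, drop = FALSE], na.rm = TRUE)
  normal_mean <- rowMeans(meth[, nor, drop = FALSE], na.rm = TRUE)
  zero <- !is.na(normal_mean) & normal_mean == 0
  if (any(zero)) {
    warning(sprintf("%d gene(s) with zero normal methylation skipped", sum(zero)))
  }
  keep <- !zero & !is.na(tumor_mean) & !is.na(normal_mean)
  df <- data.frame(
    gene_id = rownames(meth)[keep],
    tumor_mean = tumor_mean[keep],
    normal_mean = normal_mean[keep],
    ratio = tumor_mean[keep] / normal_mean[keep],
    flag = "none",
    row.names = NULL, stringsAsFactors = FALSE
  )
  df <- df[order(-df$ratio, df$gene_id), ]
  k <- round_half_up(extreme_fraction * nrow(df))
  if (k > 0 && nrow(df) > 0) {
    df$flag[seq_len(min(k, nrow(df)))] <- "hypermethylated"
    df$flag[seq(nrow(df) - min(k, nrow(df)) + 1, nrow(df))] <- "hypomethylated"
  }
  rownames(df) <- NULL
  df
}
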