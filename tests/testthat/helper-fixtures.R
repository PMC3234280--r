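# Shared fixture builders; everything is generated in code.

small_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(list(
    n_genes = 120L, n_tumor = 16L, n_normal = 4L, n_chromosomes = 3L,
    planted_fractions = c(oncogene_like = 0.1, ts_like = 0.1),
    seed = seed
  ), list(...))
  do.call(simulation_config, args)
}

make_segments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], chrom = r[[2]], start = r[[3]], end = r[[4]],
               num_info = r[[5]], seg_mean = r[[6]], stringsAsFactors = FALSE)
  }))
}

make_annotation <- function(ids, chrom, start, end, strand = NULL) {
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = strand %||% rep(".", length(ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for segment-to-gene assignment: direct
# per-gene loop over all segments, no interval machinery.
brute_force_assign <- function(segments, annotation, min_num_info = 4) {
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, nrow(annotation), length(samples),
              dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, ]
    for (i in seq_len(nrow(annotation))) {
      g <- annotation[i, ]
      over <- which(seg$chrom == g$chrom & seg$start < g$end & seg$end > g$start)
      if (length(over) != 1) next
      cover <- seg[over, ]
      if (cover$start <= g$start && cover$end >= g$end &&
          cover$num_info >= min_num_info) {
        m[i, s] <- cover$seg_mean
      }
    }
  }
  m
}

# Full-enumeration oracle for the two-sided rank-sum p-value: tabulate
# the exact U distribution over all group labelings, double the observed
# tail, cap at 1.
enumerate_rank_sum_p <- function(low, high) {
  pooled <- c(low, high)
  n1 <- length(low)
  n2 <- length(high)
  rk <- rank(pooled)
  labelings <- utils::combn(n1 + n2, n1)
  u_all <- apply(labelings, 2, function(idx) sum(rk[idx])) - n1 * (n1 + 1) / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tail <- if (u_obs > n1 * n2 / 2) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(1, 2 * tail)
}

# Step-up definition of BH: q_i = min_{j >= i} p_(j) * m / j.
step_up_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force hypergeometric upper tail by enumerating all draws of n
# from a universe of N genes whose first K are set members.
brute_force_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Explicit rank-tie-averaging oracle for quantile normalization of a
# complete matrix: each entry takes the mean of the reference values at
# every sorted position its (tied) value occupies.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    sorted_v <- sort(v)
    out[, j] <- vapply(v, function(val) mean(ref[which(sorted_v == val)]),
                       numeric(1))
  }
  out
}
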