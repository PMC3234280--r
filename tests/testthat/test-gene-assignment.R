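test_that("a fully contained gene inherits its segment's seg.mean", {
  seg <- make_segments(list("S1", "chr1", 0, 1000, 12L, 0.45))
  ann <- make_annotation("g1", "chr1", 100, 200)
  got <- assign_segments_to_genes(seg, ann, threshold_config())
  expect_identical(got["g1", "S1"], 0.45)
})

test_that("genes split across segments or in low-marker segments are missing", {
  seg <- make_segments(list("S1", "chr1", 0, 150, 12L, 0.45),
                       list("S1", "chr1", 150, 1000, 12L, 0.45),
                       list("S1", "chr2", 0, 1000, 3L, 0.9))
  ann <- make_annotation(c("split_gene", "low_info_gene", "uncovered_gene"),
                         c("chr1", "chr2", "chr3"),
                         c(100, 100, 100), c(200, 200, 200))
  got <- assign_segments_to_genes(seg, ann, threshold_config())
  expect_true(is.na(got["split_gene", "S1"]))      # spans two segments
  expect_true(is.na(got["low_info_gene", "S1"]))   # num.info < 4
  expect_true(is.na(got["uncovered_gene", "S1"]))  # no segment at all
  counts <- attr(got, "filter_counts")
  expect_identical(unname(counts["split"]), 1L)
  expect_identical(unname(counts["low_num_info"]), 1L)
})

test_that("unsorted or overlapping segments within a sample are rejected", {
  ann <- make_annotation("g1", "chr1", 100, 200)
  seg_unsorted <- make_segments(list("S1", "chr1", 500, 900, 10L, 0),
                                list("S1", "chr1", 0, 400, 10L, 0))
  expect_error(assign_segments_to_genes(seg_unsorted, ann), "not sorted")
  seg_overlap <- make_segments(list("S1", "chr1", 0, 600, 10L, 0),
                               list("S1", "chr1", 500, 900, 10L, 0))
  expect_error(assign_segments_to_genes(seg_overlap, ann), "overlap")
})

test_that("interval assignment agrees with a brute-force scan on random instances", {
  set.seed(404)
  for (rep in 1:100) {
    n_seg <- sample(2:6, 1)
    breaks <- sort(sample(1:99, n_seg - 1)) * 100
    bounds <- c(0, breaks, 10000)
    seg <- data.frame(
      sample = "S1", chrom = "chr1",
      start = bounds[-length(bounds)], end = bounds[-1],
      num_info = sample(1:10, n_seg, replace = TRUE),
      seg_mean = round(rnorm(n_seg), 3), stringsAsFactors = FALSE
    )
    n_gene <- sample(3:8, 1)
    gs <- sample(0:9900, n_gene)
    ann <- data.frame(
      gene_id = sprintf("g%02d", seq_len(n_gene)), chrom = "chr1",
      start = gs, end = gs + sample(50:2000, n_gene, replace = TRUE),
      strand = ".", stringsAsFactors = FALSE
    )
    got <- assign_segments_to_genes(seg, ann, threshold_config())
    want <- brute_force_assign(seg, ann)
    expect_equal(unclass(got)[, , drop = FALSE], want, info = paste("rep", rep))
  }
})

test_that("near-zero trimming masks the prescribed cells per sign", {
  m <- matrix(c(seq(0.1, 2.0, by = 0.1), -0.05, -1, 0, NA), 6, 4)
  rownames(m) <- paste0("g", 1:6); colnames(m) <- paste0("s", 1:4)
  out <- trim_near_zero(m, 0.05)
  # 20 positive cells -> ceiling(1) masked: the minimum positive (0.1)
  expect_identical(sum(is.na(out)) - sum(is.na(m)), 2L)  # 1 pos + 1 neg
  expect_true(is.na(out[which(m == 0.1)]))               # minimum positive
  expect_true(is.na(out[which(m == -0.05)]))             # smallest |negative|
  expect_false(is.na(out[which(m == -1)]))
  expect_identical(out[which(m == 0)], 0)                # zeros untouched

  expect_identical(trim_near_zero(m, 0), m)
  zeros <- matrix(0, 2, 2)
  expect_identical(trim_near_zero(zeros, 0.05), zeros)
  expect_error(trim_near_zero(m, 0.5), "0.5")
})

test_that("CNV states partition seg.mean space at the published thresholds", {
  cfg <- threshold_config()
  expect_identical(classify_cnv_state(0.68, cfg), "amplified")   # CCNE1 amplified mean
  expect_identical(classify_cnv_state(-0.05, cfg), "deleted")    # CCNE1 deleted mean
  expect_identical(classify_cnv_state(0.00, cfg), "neutral")     # del is strict <
  expect_identical(classify_cnv_state(0.50, cfg), "amplified")   # amp is >=
  expect_identical(classify_cnv_state(NA_real_, cfg), NA_character_)

  vals <- c(seq(-2, 2, by = 0.01), NA)
  states <- classify_cnv_state(vals, cfg)
  expect_true(all(states[!is.na(vals)] %in% c("amplified", "neutral", "deleted")))
  expect_identical(sum(is.na(states)), 1L)
})

test_that("alteration frequencies count over non-missing samples", {
  st <- rbind(
    all_del = rep("deleted", 10),
    half = c(rep("amplified", 5), rep("neutral", 5)),
    sparse = c(rep(NA, 6), "deleted", "deleted", "neutral", "neutral"),
    empty = rep(NA_character_, 10)
  )
  colnames(st) <- paste0("s", 1:10)
  freq <- alteration_frequency(st)
  expect_identical(freq$deleted[freq$gene_id == "all_del"], 1)
  expect_identical(freq$amplified[freq$gene_id == "half"], 0.5)
  expect_identical(freq$neutral[freq$gene_id == "half"], 0.5)
  expect_identical(freq$deleted[freq$gene_id == "sparse"], 0.5)
  expect_true(is.na(freq$deleted[freq$gene_id == "empty"]))
  ok <- freq$n_observed > 0
  expect_equal(freq$amplified[ok] + freq$neutral[ok] + freq$deleted[ok],
               rep(1, sum(ok)))
})

test_that("breakpoints appear only at state changes with the documented direction", {
  seg <- make_segments(list("S1", "chr1", 0, 1000, 10L, 0.3),
                       list("S1", "chr1", 1000, 2000, 10L, -0.2),
                       list("S1", "chr2", 0, 2000, 10L, 1.2),
                       list("S1", "chr3", 0, 1000, 10L, 0.0),
                       list("S1", "chr3", 1000, 2000, 10L, 0.0),
                       list("S1", "chr4", 0, 1000, 10L, 0.9),
                       list("S1", "chr4", 1000, 2000, 10L, 0.1))
  bp <- extract_breakpoints(seg, threshold_config())
  expect_identical(nrow(bp), 2L)
  b1 <- bp[bp$chrom == "chr1", ]
  expect_identical(b1$position, 1000)
  expect_identical(b1$direction, "loss")    # downstream segment is deleted
  b4 <- bp[bp$chrom == "chr4", ]
  expect_identical(b4$direction, "gain")    # transition out of amplified
})

test_that("methylation ranking flags the prescribed extremes", {
  set.seed(1)
  n <- 100
  meth <- cbind(matrix(rnorm(n * 6, 1, 0.01), n, 6),
                matrix(rnorm(n * 3, 1, 0.01), n, 3))
  rownames(meth) <- sprintf("g%03d", 1:n)
  colnames(meth) <- c(paste0("t", 1:6), paste0("n", 1:3))
  meth["g001", 1:6] <- 1.56   # hyper: ratio 1.56 = 56% increase
  meth["g002", 1:6] <- 0.5
  groups <- data.frame(sample_id = colnames(meth),
                       group = c(rep("tumor", 6), rep("normal", 3)))
  rk <- methylation_tumor_normal_ranking(meth, groups, 0.10)
  expect_identical(sum(rk$flag == "hypermethylated"), 10L)
  expect_identical(sum(rk$flag == "hypomethylated"), 10L)
  expect_equal(rk$ratio[rk$gene_id == "g001"],
               mean(meth["g001", 1:6]) / mean(meth["g001", 7:9]))
  expect_identical(rk$flag[rk$gene_id == "g001"], "hypermethylated")
  expect_identical(rk$flag[rk$gene_id == "g002"], "hypomethylated")

  # equal tumor and normal means sit mid-distribution: no flag
  mid <- rk[abs(rk$ratio - 1) < 0.002, ]
  expect_true(all(mid$flag == "none"))
})

test_that("zero normal methylation is skipped with a warning", {
  meth <- matrix(c(1, 1, 0, 0, 2, 2, 1, 1), 2, 4,
                 dimnames = list(c("gz", "g2"), c("t1", "t2", "n1", "n2")))
  meth["gz", c("n1", "n2")] <- 0
  groups <- data.frame(sample_id = colnames(meth),
                       group = c("tumor", "tumor", "normal", "normal"))
  expect_warning(rk <- methylation_tumor_normal_ranking(meth, groups, 0.1),
                 "zero normal")
  expect_false("gz" %in% rk$gene_id)
})

test_that("platform calibration recovers the reference threshold on identical data", {
  set.seed(11)
  a <- matrix(runif(700, -1.2, 0.6), 100, 7,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:7)))
  res <- calibrate_platform_threshold(a, a, colnames(a),
                                      threshold_config(),
                                      grid = seq(-1, 0, by = 0.05))
  expect_identical(res$threshold, 0)  # reference del_threshold is 0.00
  expect_identical(res$sensitivity, 1)
  expect_identical(res$fpr, 0)
})

test_that("platform calibration recovers a halved scale as half the threshold", {
  set.seed(12)
  ref <- threshold_config(del_threshold = -0.50)
  a <- matrix(runif(700, -1.2, 0.6), 100, 7,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:7)))
  b <- 0.5 * a
  res <- calibrate_platform_threshold(a, b, colnames(a), ref,
                                      grid = seq(-1, 0, by = 0.05))
  expect_identical(res$threshold, -0.25)
  expect_identical(res$sensitivity, 1)
  expect_identical(res$fpr, 0)
  expect_error(calibrate_platform_threshold(a, b, character(0), ref),
               "no shared samples")
})

test_that("quantile normalization equalizes columns and preserves ranks", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  same <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)

  set.seed(3)
  r <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  for (j in 1:4) {
    expect_equal(cor(qn[, j], r[, j], method = "spearman"), 1)
  }
})

test_that("quantile normalization ties match the rank-tie-averaging oracle", {
  m <- cbind(a = c(1, 1, 1, 2, 5), b = c(10, 20, 30, 40, 50),
             c = c(2, 2, 7, 7, 9))
  expect_equal(quantile_normalize(m), oracle_quantile_normalize(m))
  expect_error(quantile_normalize(cbind(a = c(1, NA, NA), b = c(1, 2, 3))),
               "fewer than 2")
})

test_that("MOMA fragments take max probe values and map to the closest TSS", {
  ann <- make_annotation(c("gA", "gB"), "chr1", c(1000, 8000), c(2000, 9000),
                         c("+", "+"))
  probes <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    fragment_id = c("f1", "f1", "f2"),
    chrom = "chr1",
    start = c(700, 800, 7500), end = c(750, 850, 7550),
    s1 = c(0.8, 1.2, 2.0), s2 = c(0.5, 0.4, 1.1),
    stringsAsFactors = FALSE
  )
  got <- assign_methylation_to_genes(probes, ann, "moma_ratio")
  # f1 midpoint 775 -> nearest TSS is gA start (1000); max probe = 1.2 / 0.5
  expect_identical(got["gA", "s1"], 1.2)
  expect_identical(got["gA", "s2"], 0.5)
  # f2 midpoint 7525 -> gB; single probe
  expect_identical(got["gB", "s1"], 2.0)
})

test_that("multiple fragments per gene combine by max; beta genes need 2 probes", {
  ann <- make_annotation("gA", "chr1", 1000, 2000, "+")
  probes <- data.frame(
    probe_id = c("p1", "p2"), fragment_id = c("f1", "f2"), chrom = "chr1",
    start = c(700, 2100), end = c(750, 2150),
    s1 = c(0.9, 1.4), stringsAsFactors = FALSE
  )
  got <- assign_methylation_to_genes(probes, ann, "moma_ratio")
  expect_identical(got["gA", "s1"], 1.4)

  beta <- data.frame(
    probe_id = c("p1", "p2", "p3"), gene_id = c("gA", "gA", "gB"),
    chrom = "chr1", start = c(1, 2, 3), end = c(2, 3, 4),
    s1 = c(0.2, 0.4, 0.9), stringsAsFactors = FALSE
  )
  ann2 <- make_annotation(c("gA", "gB"), "chr1", c(0, 100), c(50, 150))
  got2 <- assign_methylation_to_genes(beta, ann2, "beta")
  expect_equal(got2["gA", "s1"], 0.3)            # mean of two probes
  expect_true(is.na(got2["gB", "s1"]))           # single probe -> missing
})
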