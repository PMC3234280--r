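test_that("extreme-CNV gene selection honors the sample-fraction gate", {
  samples <- paste0("s", 1:10)
  cnv <- rbind(
    amp30 = c(rep(0.8, 3), rep(0, 7)),
    amp10 = c(0.8, rep(0, 9)),
    dual = c(rep(0.9, 3), rep(-0.9, 3), rep(0, 4)),
    flat = rep(0.1, 10)
  )
  colnames(cnv) <- samples
  cfg <- threshold_config(min_sample_fraction = 0.2)
  sets <- select_extreme_cnv_genes(cnv, cfg)
  expect_true("amp30" %in% sets$amplified)
  expect_false("amp10" %in% sets$amplified)
  expect_true("dual" %in% sets$amplified)
  expect_true("dual" %in% sets$deleted)         # dual membership allowed
  expect_false("flat" %in% sets$amplified)
})

test_that("tumor:normal ratios use linear means and a deterministic bootstrap", {
  expr_t <- matrix(3, 1, 4, dimnames = list("g1", paste0("t", 1:4)))  # 2^3 = 8
  expr_n <- matrix(2, 1, 2, dimnames = list("g1", paste0("n", 1:2)))  # 2^2 = 4
  r <- tumor_normal_expression_ratio(expr_t, expr_n, seed = 1)
  expect_equal(r$ratio, 2)
  expect_identical(r$normal_source, "native")

  # a singleton donor resamples to itself regardless of reps
  donor <- matrix(2.5, 1, 1, dimnames = list("g1", "d1"))
  rb <- tumor_normal_expression_ratio(expr_t, NULL, donor,
                                      bootstrap_reps = 50, seed = 1)
  expect_equal(rb$normal_mean, 2^2.5)
  expect_identical(rb$normal_source, "bootstrap")

  # bootstrap determinism under a fixed seed
  set.seed(99)
  donor2 <- matrix(rnorm(6, 3, 1), 1, 6,
                   dimnames = list("g1", paste0("d", 1:6)))
  r1 <- tumor_normal_expression_ratio(expr_t, NULL, donor2, seed = 42)
  r2 <- tumor_normal_expression_ratio(expr_t, NULL, donor2, seed = 42)
  expect_identical(r1, r2)
  # no normal information anywhere -> NA ratio
  r3 <- tumor_normal_expression_ratio(expr_t, NULL, NULL, seed = 1)
  expect_true(is.na(r3$ratio))
  expect_identical(r3$normal_source, "absent")
})

test_that("quantile thresholds interpolate the prescribed cutpoints", {
  qt <- compute_quantile_thresholds(1:5, 1:5, q = 0.25)
  expect_equal(qt$ratio_low, 2)
  expect_equal(qt$ratio_high, 4)
  qt50 <- compute_quantile_thresholds(1:5, 1:5, q = 0.5)
  expect_equal(qt50$ratio_low, qt50$ratio_high)   # both at the median
  same <- compute_quantile_thresholds(rep(2, 6), rep(2, 6))
  expect_equal(same$ratio_low, same$ratio_high)
  expect_error(compute_quantile_thresholds(1:3, 1:5), "at least 4")
})

test_that("feature quadrants are assigned per the joint rule", {
  samples <- paste0("t", 1:10)
  cnv <- rbind(
    onc = c(rep(1, 4), rep(0, 6)),
    amp_sup = c(rep(1, 4), rep(0, 6)),
    amp_mid = c(rep(1, 4), rep(0, 6)),
    ts = c(rep(-1, 4), rep(0, 6)),
    del_exp = c(rep(-1, 4), rep(0, 6))
  )
  colnames(cnv) <- samples
  meth <- matrix(1, 5, 10, dimnames = dimnames(cnv))
  meth["onc", 1:4] <- 0.6
  meth["amp_sup", 1:4] <- 1.4
  meth["ts", 1:4] <- 1.4
  meth["del_exp", 1:4] <- 0.6
  ratios <- data.frame(
    gene_id = rownames(cnv),
    ratio = c(2, 0.5, 1.0, 0.5, 2),
    stringsAsFactors = FALSE
  )
  thresholds <- list(ratio_low = 0.8, ratio_high = 1.5,
                     meth_low = 0.9, meth_high = 1.1)
  calls <- classify_features(cnv, meth, ratios, thresholds,
                             threshold_config(min_sample_fraction = 0.2))
  get_class <- function(g) calls$feature_class[calls$gene_id == g]
  expect_identical(get_class("onc"), "oncogene_like")
  expect_identical(get_class("amp_sup"), "amplified_suppressed")
  expect_identical(get_class("amp_mid"), "none")   # middling ratio
  expect_identical(get_class("ts"), "ts_like")
  expect_identical(get_class("del_exp"), "deleted_expressed")
  # one feature class per (gene, cnv class) row
  expect_identical(anyDuplicated(calls[c("gene_id", "cnv_class")]), 0L)
})

test_that("group means, Euclidean distances and degenerate tests behave", {
  # tumor means (0,0), normal means (3,4): joint distance 5
  meth <- rbind(g1 = c(-1, 1, 0, 0, 3, 3))
  expr <- rbind(g1 = c(2, -2, 1, -1, 4, 4))
  colnames(meth) <- colnames(expr) <- c(paste0("t", 1:4), "n1", "n2")
  groups <- data.frame(sample_id = colnames(meth),
                       group = c(rep("tumor", 4), rep("normal", 2)))
  res <- normal_vs_tumor_significance(meth, expr, groups)
  expect_equal(res$euclid_meth, 3)
  expect_equal(res$euclid_expr, 4)
  expect_equal(res$euclid_joint, 5)

  # equal means -> zero distances, zero T^2
  set.seed(8)
  m2 <- rbind(g1 = c(-1, 1, -1, 1, -2, 2))
  colnames(m2) <- colnames(meth)
  ht <- tsoscan:::hotelling_t2(cbind(m2[1, 1:4], m2[1, 1:4] * 2),
                               cbind(m2[1, 5:6], m2[1, 5:6] * 2))
  expect_equal(ht$t2, 0)
})

test_that("identical distributions give near-1 p-values", {
  set.seed(31)
  vals <- rnorm(40)
  x <- cbind(vals[1:20], rnorm(20))
  y <- cbind(vals[1:20], rnorm(20))  # same first coordinate distribution
  y[, 1] <- x[, 1]
  ht <- tsoscan:::hotelling_t2(x, y)
  expect_gt(ht$p_value, 0.5)
})

test_that("Hotelling T^2 collapses to the squared Welch t under perfect correlation", {
  a <- c(1.2, 2.5, 3.1, 4.8, 2.2)
  b <- c(3.4, 4.1, 5.9, 6.2)
  ht <- tsoscan:::hotelling_t2(cbind(a, a), cbind(b, b))
  tstat <- unname(t.test(a, b)$statistic)
  expect_equal(ht$t2, tstat^2)
  expect_true(is.na(ht$p_value))    # singular covariance: p stays missing
})

test_that("percentile ranking maps q-values onto [0, 100]", {
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      q_multi = c(0.001, 0.01, 0.04, 0.2),
                      stringsAsFactors = FALSE)
  out <- percentile_rank_calls(calls, 0.05)
  expect_equal(out$percentile_rank[1:3], c(100, 50, 0))
  expect_true(is.na(out$percentile_rank[4]))

  single <- percentile_rank_calls(
    data.frame(gene_id = "a", q_multi = 0.01), 0.05)
  expect_equal(single$percentile_rank, 100)

  none <- percentile_rank_calls(
    data.frame(gene_id = "a", q_multi = 0.5), 0.05)
  expect_true(is.na(none$percentile_rank))
})

test_that("planted main-quadrant classes are recovered on a strong-effect cohort", {
  # the additive expression model makes the cross quadrants reachable only
  # when the methylation term dominates dosage; the main quadrants
  # (oncogene-like, TS-like) are the recovery benchmark here
  co <- generate_cohort(small_config(
    seed = 19, n_genes = 300, n_tumor = 40, n_normal = 6,
    planted_fractions = c(oncogene_like = 0.05, ts_like = 0.05)
  ))
  thr <- threshold_config(high_screen_threshold = 0.5,
                          low_screen_threshold = -0.5)
  ratios <- tumor_normal_expression_ratio(co$expr_tumor, co$expr_normal,
                                          seed = 19)
  meth_t <- co$methylation[, colnames(co$cnv)]
  qt <- compute_quantile_thresholds(ratios$ratio, rowMeans(meth_t))
  calls <- classify_features(co$cnv, co$methylation, ratios, qt, thr)
  planted <- co$truth[co$truth$class != "null", ]
  hit <- merge(planted, calls, by = "gene_id", all.x = TRUE)
  recovery <- sum(hit$class == hit$feature_class, na.rm = TRUE) / nrow(planted)
  expect_gt(recovery, 0.9)
  null_named <- calls$gene_id[calls$feature_class != "none"]
  null_rate <- mean(co$truth$gene_id[co$truth$class == "null"] %in% null_named)
  expect_lt(null_rate, 0.05)
})

test_that("cross quadrants are recovered when the methylation term dominates", {
  co <- generate_cohort(small_config(
    seed = 29, n_genes = 300, n_tumor = 40, n_normal = 6,
    planted_fractions = c(amplified_suppressed = 0.05, deleted_expressed = 0.05),
    cnv_effect = 0.8, expr_dosage_slope = 0.5,
    meth_effect = 0.6, meth_coupling = 2.0
  ))
  thr <- threshold_config(high_screen_threshold = 0.5,
                          low_screen_threshold = -0.5)
  ratios <- tumor_normal_expression_ratio(co$expr_tumor, co$expr_normal,
                                          seed = 29)
  qt <- compute_quantile_thresholds(ratios$ratio,
                                    rowMeans(co$methylation[, colnames(co$cnv)]))
  calls <- classify_features(co$cnv, co$methylation, ratios, qt, thr)
  planted <- co$truth[co$truth$class != "null", ]
  hit <- merge(planted, calls, by = "gene_id", all.x = TRUE)
  recovery <- sum(hit$class == hit$feature_class, na.rm = TRUE) / nrow(planted)
  expect_gt(recovery, 0.8)
})
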