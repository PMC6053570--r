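## a compact design frame for direct fit tests
toy_design <- function() {
  st <- default_study()
  prep <- prep_study(st)
  cln_design(prep$metadata)
}

test_that("eligibility applies the positive-count rules", {
  design <- toy_design()
  spec <- cln_spec("region")
  n <- nrow(design)
  ## all-positive feature: eligible, binary part degenerate
  el <- cln_eligibility(rep(2, n), spec, design)
  expect_true(el$eligible)
  expect_true(el$all_positive)
  ## a single positive observation
  y1 <- c(5, rep(0, n - 1))
  expect_equal(cln_eligibility(y1, spec, design)$reason,
               "insufficient_positives")
  ## all-zero feature
  expect_equal(cln_eligibility(rep(0, n), spec, design)$reason, "all_zero")
  ## enough positives overall but a bare factor level
  y2 <- rep(0, n)
  y2[which(design$region == "eastern_jutland")[1:10]] <- 3
  expect_equal(cln_eligibility(y2, spec, design)$reason,
               "level_without_positives")
  ## a continuous factor only needs the total-count rule
  expect_true(cln_eligibility(y2, cln_spec("leaf_area"), design)$eligible)
})

test_that("eligible counts per factor fall in the study-like band", {
  st <- default_study()
  prep <- prep_study(st)
  design <- cln_design(prep$metadata)
  for (f in c("region", "habitat", "light", "soil_ph", "leaf_status")) {
    spec <- cln_spec(f)
    n_el <- sum(vapply(seq_len(ncol(prep$table$intensities)), function(j) {
      cln_eligibility(prep$table$intensities[, j], spec, design)$eligible
    }, logical(1)))
    expect_gte(n_el, 170)
    expect_lte(n_el, 197)
  }
})

test_that("combined LR arithmetic and chi-square reference", {
  t1 <- combined_lr_test(delta_ll = c(1, 2), df = c(2, 2))
  expect_equal(t1$lr, 6)
  expect_equal(t1$df, 4)
  t2 <- combined_lr_test(delta_ll = 5.99 / 2, df = 2)
  expect_equal(t2$p, 0.05, tolerance = 1e-3)
  ## identical fits
  t3 <- combined_lr_test(delta_ll = 0, df = 2)
  expect_equal(t3$lr, 0)
  expect_equal(t3$p, 1)
  ## negative LR beyond tolerance is flagged and clamped
  t4 <- combined_lr_test(delta_ll = -1, df = 2)
  expect_equal(t4$flag, "negative_lr")
  expect_equal(t4$lr, 0)
})

test_that("Fisher combination of part-wise p-values", {
  expect_equal(fisher_combine(0.25)$p, 0.25)
  f <- fisher_combine(c(0.1, 0.2))
  expect_equal(f$stat, -2 * (log(0.1) + log(0.2)))
  expect_equal(f$df, 4L)
  expect_equal(f$p, pchisq(f$stat, 4, lower.tail = FALSE))
  expect_true(is.na(fisher_combine(NA_real_)$p))
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  ## NA p-values stay NA and do not count towards m
  q <- fdr_bh(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  ## monotone in the ranked p-values; q >= p
  set.seed(12)
  p <- runif(50)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("a planted region effect is detected and an all-positive feature skips the binary part", {
  st <- default_study()
  prep <- prep_study(st)
  design <- cln_design(prep$metadata)
  spec <- cln_spec("region")
  tr <- st$truth[match(prep$table$feature_ids, st$truth$feature_id), ]
  ## strongly planted region feature -> very small combined p
  j <- which(tr$affected_by == "region")[1]
  fit <- suppressWarnings(suppressMessages(
    fit_cln(prep$table$intensities[, j], design, spec)))
  expect_lt(fit$test$p, 0.001)
  ## all-positive feature -> binary df 0, test from the positive part alone
  set.seed(51)
  y_all <- exp(rnorm(nrow(design), 4, 0.5))
  fit2 <- suppressWarnings(suppressMessages(fit_cln(y_all, design, spec)))
  expect_equal(fit2$binary$df, 0L)
  expect_equal(fit2$binary$engine, "none")
  expect_equal(fit2$test$p, fit2$positive$p)
})

test_that("the additive-LR construction remains available as a method", {
  st <- default_study()
  prep <- prep_study(st)
  design <- cln_design(prep$metadata)
  spec <- cln_spec("region", method = "lr_additive")
  tr <- st$truth[match(prep$table$feature_ids, st$truth$feature_id), ]
  j <- which(tr$affected_by == "region")[2]
  fit <- suppressWarnings(suppressMessages(
    fit_cln(prep$table$intensities[, j], design, spec)))
  ## additive chi-square: stat = 2 * sum of part-wise LL differences
  expect_equal(fit$test$stat,
               2 * ((fit$binary$ll_full - fit$binary$ll_red) +
                    (fit$positive$ll_full - fit$positive$ll_red)),
               tolerance = 1e-8)
  expect_equal(fit$test$df, fit$binary$df + fit$positive$df)
  expect_lt(fit$test$p, 0.001)
})

test_that("cln_analysis returns a consistent per-feature table", {
  st <- generate_study(small_config(), seed = 21)
  md <- st$metadata
  qf <- qc_rsd_filter(normalize_total_intensity(st$table),
                      md$sample_id[md$role == "qc"])
  avg <- average_replicates(qf$table, md)
  res <- cln_analysis(avg$table, avg$metadata, "region")
  expect_s3_class(res, "cln_result")
  expect_equal(nrow(res), ncol(avg$table$intensities))
  tested <- !is.na(res$p)
  expect_true(all(res$p[tested] >= 0 & res$p[tested] <= 1))
  expect_true(all(res$q[tested] >= res$p[tested] - 1e-12))
  expect_true(all(res$df[tested] >= 1))
  ## tallies recount the result columns
  tl <- significance_tallies(res)
  expect_equal(tl$n_used, sum(tested))
  expect_equal(tl$q_lt_0.20, sum(res$q < 0.20, na.rm = TRUE))
  expect_equal(tl$p_lt_0.001, sum(res$p < 0.001, na.rm = TRUE))
  ## planted region features dominate the q < 0.20 calls
  tr <- st$truth[match(res$feature_id, st$truth$feature_id), ]
  sig <- !is.na(res$q) & res$q < 0.20
  expect_gte(sum(sig & tr$affected_by == "region"), 7)
})

test_that("Tukey post hoc contrasts isolate the planted region block", {
  st <- default_study()
  prep <- prep_study(st)
  tr <- st$truth[match(prep$table$feature_ids, st$truth$feature_id), ]
  fid <- tr$feature_id[which(tr$region_block == "western_jutland")[1]]
  ph <- suppressWarnings(suppressMessages(
    tukey_posthoc(prep$table, prep$metadata, "region", fid)))
  expect_equal(nrow(ph), 3L)  # all level pairs of a 3-level factor
  wj <- grepl("western_jutland", ph$contrast)
  expect_true(all(ph$p_tukey[wj] < 0.05))
  expect_gt(ph$p_tukey[!wj], 0.05)
  ## a 2-level factor collapses to the unadjusted contrast
  ph2 <- suppressWarnings(suppressMessages(
    tukey_posthoc(prep$table, prep$metadata, "leaf_status", fid)))
  expect_equal(nrow(ph2), 1L)
  expect_error(tukey_posthoc(prep$table, prep$metadata, "leaf_area", fid),
               "categorical")
})
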