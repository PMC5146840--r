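test_that("identical case and control genotype distributions give a null fit", {
  dosage <- rep(c(0, 1, 1, 2), 10)
  coh <- cohort_table(data.frame(
    sample_id = sprintf("s%02d", 1:80), study = "a",
    status = rep(c(0L, 1L), each = 40),
    age = rep(rep(c(40, 55), 20), 2),
    rs_null = c(dosage, dosage)
  ))
  fit <- fit_snp(coh, "rs_null")
  expect_true(is.na(fit$flag))
  expect_equal(fit$log_or_hat, 0, tolerance = 1e-8)
  expect_equal(fit$p_one_sided, 0.5, tolerance = 1e-7)
})

test_that("the logistic MLE matches a likelihood grid-search oracle to 1e-4", {
  coh <- fixture20()
  fit <- fit_snp(coh, "rs_fix", covariates = character(0))
  oracle <- grid_logistic_mle(coh$status, coh$rs_fix)
  expect_equal(fit$log_or_hat, unname(oracle["slope"]), tolerance = 1e-4)
})

test_that("simulated per-allele effects are recovered within sampling error", {
  cfg <- sim_config(n_snps = 1, prevalence = 0.05,
                    freq_range = c(0.5, 0.5), log_or_range = c(log(2), log(2)),
                    studies = data.frame(study = "a", n_cases = 5000L,
                                         n_controls = 5000L),
                    seed = 21)
  pan <- generate_panel(cfg)
  coh <- generate_cohort(pan, cfg)
  fit <- fit_snp(coh, pan$snp_id[1])
  expect_true(is.na(fit$flag))
  expect_lt(abs(fit$log_or_hat - log(2)), 3 * fit$se)
})

test_that("monomorphic and degenerate fits are flagged, not fatal", {
  coh <- cohort_table(data.frame(
    sample_id = sprintf("s%d", 1:20), study = "a",
    status = rep(c(0L, 1L), 10), age = 50,
    rs_mono = rep(2, 20),
    rs_sep = rep(c(0, 2), 10)  # dosage perfectly predicts status
  ))
  expect_equal(fit_snp(coh, "rs_mono")$flag, "monomorphic")
  fit <- fit_snp(coh, "rs_sep", covariates = character(0))
  expect_false(is.na(fit$flag))
  expect_error(fit_snp(coh, "rs_absent"), "rs_absent")
})

test_that("fixed-effect pooling obeys its closed-form identities", {
  # a single study passes through unchanged
  m1 <- meta_fixed(0.12, 0.05)
  expect_equal(m1$pooled_log_or, 0.12)
  expect_equal(m1$pooled_se, 0.05)
  expect_true(is.na(m1$heterogeneity_p))

  # equal standard errors: arithmetic mean, se / sqrt(2)
  m2 <- meta_fixed(c(0.1, 0.2), c(0.05, 0.05))
  expect_equal(m2$pooled_log_or, 0.15)
  expect_equal(m2$pooled_se, 0.05 / sqrt(2))

  # k copies of one study: same estimate, se / sqrt(k)
  m5 <- meta_fixed(rep(0.12, 5), rep(0.05, 5))
  expect_equal(m5$pooled_log_or, 0.12)
  expect_equal(m5$pooled_se, 0.05 / sqrt(5))
  expect_equal(m5$heterogeneity_Q, 0)

  # three unequal studies: hand-computed inverse-variance average
  b <- c(0.10, 0.25, -0.05)
  se <- c(0.08, 0.12, 0.20)
  w <- 1 / se^2
  m3 <- meta_fixed(b, se)
  expect_equal(m3$pooled_log_or, sum(w * b) / sum(w))
  expect_equal(m3$pooled_se, 1 / sqrt(sum(w)))
  expect_equal(m3$heterogeneity_Q, sum(w * (b - m3$pooled_log_or)^2))
  # pooled se never exceeds the best single study
  expect_lte(m3$pooled_se, min(se))

  expect_error(meta_fixed(numeric(0), numeric(0)), "no usable")
})

test_that("fixed-effect pooling agrees with an independent implementation", {
  b <- c(0.10, 0.25, -0.05)
  se <- c(0.08, 0.12, 0.20)
  ours <- meta_fixed(b, se)
  ref <- metafor::rma(yi = b, sei = se, method = "FE")
  expect_equal(ours$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$pooled_se, ref$se, tolerance = 1e-10)
  expect_equal(ours$heterogeneity_Q, ref$QE, tolerance = 1e-10)
})

test_that("pooled precision strictly increases as studies accumulate", {
  se <- c(0.1, 0.15, 0.08, 0.3)
  b <- c(0.1, 0.12, 0.09, 0.2)
  ses <- vapply(seq_along(b), function(k) {
    meta_fixed(b[seq_len(k)], se[seq_len(k)])$pooled_se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("selection filters on one-sided p and keeps the best SNP per locus", {
  pan <- snp_panel(paste0("rs", 1:4), c("l1", "l1", "l2", "l3"),
                   "A", rep(0.3, 4), rep(0.1, 4))
  meta <- data.frame(
    snp_id = paste0("rs", 1:4),
    pooled_log_or = c(0.10, 0.12, 0.08, 0.02),
    pooled_se = rep(0.03, 4),
    p_one_sided = c(0.03, 0.01, 0.20, 0.04)
  )
  # alpha = 1: nothing dropped by significance, one SNP per locus remains
  sel_all <- select_snps(meta, pan, alpha = 1)
  expect_equal(nrow(sel_all), 3)
  # alpha = 0.05: locus l2 fails replication; l1 keeps its min-p member
  sel <- select_snps(meta, pan, alpha = 0.05)
  expect_setequal(sel$snp_id, c("rs2", "rs4"))
  # selected weights are the pooled estimates...
  expect_equal(sel$log_or[sel$snp_id == "rs2"], 0.12)
  # ...unless the externally reported weights are requested
  sel_ext <- select_snps(meta, pan, alpha = 0.05, weights = "panel")
  expect_equal(sel_ext$log_or[sel_ext$snp_id == "rs2"], 0.1)

  # equal p within a locus: lexicographically smallest snp_id wins
  meta_tie <- meta
  meta_tie$p_one_sided <- c(0.01, 0.01, 0.2, 0.04)
  expect_true("rs1" %in% select_snps(meta_tie, pan, alpha = 0.05)$snp_id)

  meta_bad <- meta
  meta_bad$snp_id[1] <- "rs99"
  expect_error(select_snps(meta_bad, pan), "not in the panel")
})

test_that("one-sided p-values honour the a-priori risk-allele direction", {
  # a protective reported allele (negative panel log OR): a negative
  # estimate supports replication, a positive one does not
  set.seed(9)
  n <- 4000
  dose <- stats::rbinom(n, 2, 0.4)
  status <- stats::rbinom(n, 1, stats::plogis(-1 - 0.3 * dose))
  coh <- cohort_table(data.frame(sample_id = as.character(1:n), study = "a",
                                 status = status, age = 50, rs_p = dose))
  fit_pos <- fit_snp(coh, "rs_p", direction = 1)
  fit_neg <- fit_snp(coh, "rs_p", direction = -1)
  expect_lt(fit_neg$p_one_sided, 0.05)
  expect_equal(fit_pos$p_one_sided + fit_neg$p_one_sided, 1, tolerance = 1e-9)
})
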