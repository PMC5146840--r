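test_that("panel generation is seed-deterministic and honours its ranges", {
  cfg <- sim_config(n_snps = 44, seed = 1)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 44)
  expect_false(anyDuplicated(p1$locus_id) > 0)
  expect_true(all(p1$effect_allele_freq >= 0.1 & p1$effect_allele_freq <= 0.9))
  expect_true(all(p1$log_or >= 0.02 & p1$log_or <= 0.25))

  # different seed, different panel
  expect_false(identical(generate_panel(sim_config(n_snps = 44, seed = 2)), p1))

  # sd_target rescaling pins the theoretical score SD exactly
  pt <- generate_panel(sim_config(n_snps = 44, sd_target = 0.38, seed = 1))
  expect_equal(prs_model(pt)$sigma, 0.38, tolerance = 1e-12)
})

test_that("a null architecture yields zero effects and zero score variance", {
  cfg <- sim_config(n_snps = 10, log_or_range = c(0, 0), seed = 3)
  pan <- generate_panel(cfg)
  expect_true(all(pan$log_or == 0))
  expect_equal(prs_model(pan)$sigma2, 0)
})

test_that("cohort generation is deterministic and meets the requested design", {
  cfg <- sim_config(n_snps = 4, prevalence = 0.05,
                    studies = data.frame(study = c("a", "b"),
                                         n_cases = c(120L, 80L),
                                         n_controls = c(150L, 90L)),
                    age_range = c(30, 60), seed = 11)
  pan <- generate_panel(cfg)
  c1 <- generate_cohort(pan, cfg)
  c2 <- generate_cohort(pan, cfg)
  expect_identical(c1, c2)
  counts <- table(c1$study, c1$status)
  expect_equal(unname(counts["a", "1"]), 120)
  expect_equal(unname(counts["a", "0"]), 150)
  expect_equal(unname(counts["b", "1"]), 80)
  expect_equal(unname(counts["b", "0"]), 90)
  dos <- as.matrix(c1[, pan$snp_id])
  expect_true(all(dos %in% 0:2))
  expect_true(all(c1$age >= 30 & c1$age <= 60))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(prevalence = 1), "prevalence")
  expect_error(sim_config(freq_range = c(0.9, 0.1)), "ordered")
  expect_error(sim_config(freq_range = c(0, 0.5)), "\\(0, 1\\)")
  expect_error(sim_config(studies = data.frame(study = "a", n_cases = 0L,
                                               n_controls = 10L)), "positive")
  expect_error(sim_config(sd_target = -1), "sd_target")
})

test_that("control genotype frequencies follow Hardy-Weinberg at low prevalence", {
  sim <- control_sim()
  ctrl <- sim$cohort[sim$cohort$status == 0, ]
  n <- nrow(ctrl)
  p <- sim$panel$effect_allele_freq
  for (j in seq_len(nrow(sim$panel))) {
    expected <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    observed <- tabulate(ctrl[[sim$panel$snp_id[j]]] + 1, nbins = 3) / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(observed - expected) < 4 * se),
                info = paste("HWE deviation at", sim$panel$snp_id[j]))
  }
})

test_that("with no genetic effects, case and control genotypes are exchangeable", {
  cfg <- sim_config(n_snps = 3, log_or_range = c(0, 0), prevalence = 0.2,
                    studies = data.frame(study = "a", n_cases = 4000L,
                                         n_controls = 4000L), seed = 5)
  pan <- generate_panel(cfg)
  coh <- generate_cohort(pan, cfg)
  for (id in pan$snp_id) {
    tab <- table(factor(coh[[id]], levels = 0:2), coh$status)
    expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  }
})

test_that("the simulator's realized case fraction matches the calibrated prevalence", {
  # with all betas = 0 the disease probability is the same for everyone,
  # so the calibrated intercept can be checked directly
  cfg <- sim_config(n_snps = 2, log_or_range = c(0, 0), prevalence = 0.13,
                    seed = 2)
  pan <- generate_panel(cfg)
  expect_equal(stats::plogis(prstrat:::calibrate_intercept(pan, 0.13)),
               0.13, tolerance = 1e-7)
  # and with real effects the quadrature-calibrated population risk is exact
  pan2 <- generate_panel(sim_config(n_snps = 20, sd_target = 0.38, seed = 2))
  ic <- prstrat:::calibrate_intercept(pan2, 0.01)
  m <- prs_model(pan2)
  risk <- stats::integrate(function(s) stats::plogis(ic + s) *
                             stats::dnorm(s, m$mu, m$sigma),
                           -Inf, Inf)$value
  expect_equal(risk, 0.01, tolerance = 1e-6)
})

test_that("control score moments converge to the theoretical mean and SD", {
  sim <- control_sim()
  ctrl <- sim$cohort[sim$cohort$status == 0, ]
  class(ctrl) <- class(sim$cohort)
  s <- compute_prs(ctrl, sim$panel)
  n <- length(s)
  m <- sim$model
  expect_lt(abs(mean(s) - m$mu), 3 * m$sigma / sqrt(n))
  expect_lt(abs(stats::sd(s) - m$sigma), 3 * m$sigma / sqrt(2 * n))
})

test_that("case scores are shifted above controls by the score variance", {
  # rare disease, small effects: E[PRS | case] - E[PRS | control] ~ sigma^2
  sim <- big_sim()
  expect_true(all(abs(sim$panel$log_or) <= 0.3))
  s <- sim$scores
  status <- sim$cohort$status
  shift <- mean(s[status == 1]) - mean(s[status == 0])
  se <- sim$model$sigma * sqrt(1 / sum(status == 1) + 1 / sum(status == 0))
  expect_lt(abs(shift - sim$model$sigma2), 3 * se)
})

test_that("rate-table generation calibrates cumulative risk to the target", {
  rt <- generate_rate_table(target_lifetime_risk = 0.0364)
  expect_equal(absolute_risk(rt, or = 1, alpha = 20, tau = 60), 0.0364,
               tolerance = 1e-6 / 0.0364)
  expect_equal(rt$mortality, prstrat:::default_mortality_shape / 1e5)

  # zero incidence: zero risk at any horizon
  rt0 <- generate_rate_table(target_lifetime_risk = 0)
  expect_equal(absolute_risk(rt0, or = 1, alpha = 20, tau = 60), 0)

  expect_error(generate_rate_table(incidence_per_100k = rep(-1, 12)),
               "non-negative")
  expect_error(generate_rate_table(incidence_per_100k = 1:3),
               "per age band")
})

test_that("PAR-aware calibration pins the reference band's absolute risk", {
  par38 <- polygenic_par(0.38)
  rt <- generate_rate_table(target_lifetime_risk = 0.0364, par = par38)
  st <- stratify(0.38)
  tab <- risk_table(rt, st, alpha = 20, tau = 60)
  ref <- tab$risk[tab$u == 0.4 & tab$v == 0.6]
  expect_equal(ref, 0.0364, tolerance = 1e-6 / 0.0364)
})
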