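# Shared fixtures, all generated in code. Expensive simulations are built
# once per test run and cached for every file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Large case-control cohort under the target architecture: 44 SNPs scaled
# to score SD 0.38, rare disease (1%), 25k cases / 75k controls.
big_sim <- function() {
  cache_get("big_sim", function() {
    cfg <- sim_config(
      n_snps = 44, sd_target = 0.38, prevalence = 0.01,
      studies = data.frame(study = "s1", n_cases = 25000L,
                           n_controls = 75000L),
      seed = 42
    )
    panel <- generate_panel(cfg)
    cohort <- generate_cohort(panel, cfg)
    model <- prs_model(panel)
    list(cfg = cfg, panel = panel, cohort = cohort, model = model,
         scores = compute_prs(cohort, panel))
  })
}

# Control-heavy cohort at very low prevalence (0.2%), where the control
# score distribution is indistinguishable from the population's.
control_sim <- function() {
  cache_get("control_sim", function() {
    cfg <- sim_config(
      n_snps = 44, sd_target = 0.38, prevalence = 0.002,
      studies = data.frame(study = "s1", n_cases = 10L,
                           n_controls = 50000L),
      seed = 7
    )
    panel <- generate_panel(cfg)
    list(cfg = cfg, panel = panel, cohort = generate_cohort(panel, cfg),
         model = prs_model(panel))
  })
}

# Fixed 20-subject, one-SNP dataset for the logistic-likelihood oracle.
fixture20 <- function() {
  dosage <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2, 0, 1, 2, 2, 1, 0, 1, 2, 0, 1)
  status <- c(0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 1, 0, 1)
  cohort_table(data.frame(
    sample_id = sprintf("s%02d", 1:20), study = "fix", status = status,
    age = rep(50, 20), rs_fix = dosage
  ))
}

# Brute-force maximizer of the Bernoulli log-likelihood of
# logit P(y=1) = a + b x over an (a, b) grid, refined around the optimum.
# Independent of glm: direct likelihood evaluation only.
grid_logistic_mle <- function(y, x, n_grid = 41, n_zoom = 9) {
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  width <- c(10, 10)
  for (z in seq_len(n_zoom)) {
    a_grid <- seq(centre[1] - width[1], centre[1] + width[1],
                  length.out = n_grid)
    b_grid <- seq(centre[2] - width[2], centre[2] + width[2],
                  length.out = n_grid)
    ll <- outer(a_grid, b_grid, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    centre <- c(a_grid[best[1]], b_grid[best[2]])
    width <- width * 2.5 / (n_grid - 1)  # keep neighbours of the best cell
  }
  c(intercept = centre[1], slope = centre[2])
}

# Empirical odds ratios by score band, cut at the model quantiles of the
# population score distribution and referenced to the 40-60 band.
empirical_band_or <- function(scores, status, bands, model) {
  qs_lo <- stats::qnorm(bands$u, model$mu, model$sigma)
  qs_hi <- stats::qnorm(bands$v, model$mu, model$sigma)
  ref_lo <- stats::qnorm(0.4, model$mu, model$sigma)
  ref_hi <- stats::qnorm(0.6, model$mu, model$sigma)
  ref_cases <- sum(status == 1 & scores >= ref_lo & scores < ref_hi)
  ref_ctrls <- sum(status == 0 & scores >= ref_lo & scores < ref_hi)
  out <- lapply(seq_len(nrow(bands)), function(j) {
    inb <- scores >= qs_lo[j] & scores < qs_hi[j]
    n1 <- sum(status == 1 & inb)
    n0 <- sum(status == 0 & inb)
    data.frame(u = bands$u[j], v = bands$v[j],
               or = (n1 / n0) / (ref_cases / ref_ctrls),
               se_log = sqrt(1 / n1 + 1 / n0 + 1 / ref_cases + 1 / ref_ctrls))
  })
  do.call(rbind, out)
}
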