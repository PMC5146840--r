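#' Compute polygenic risk scores
#'
#' The PRS of an individual is the weighted dosage sum
#' \eqn{\sum_i \beta_i x_i} over the panel SNPs, with \eqn{\beta_i} the
#' per-allele log odds ratio and \eqn{x_i \in [0,2]} the effect-allele
#' dosage. A missing dosage is mean-imputed as \eqn{2 p_i}, its
#' Hardy-Weinberg expectation.
#'
#' @param cohort a [cohort_table()]; every panel SNP must be a dosage column.
#' @param panel a [snp_panel()] of selected, weighted SNPs.
#' @return Numeric vector of scores, named by `sample_id`, aligned to the
#'   cohort rows.
#' @export
#' @examples
#' pan <- snp_panel("rs1", "l1", "A", 0.5, 0.1)
#' coh <- cohort_table(data.frame(sample_id = "s1", study = "a", status = 0L,
#'                                age = 50, rs1 = 2))
#' compute_prs(coh, pan)  # 0.2
compute_prs <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(panel, "snp_panel"))
  missing_snps <- setdiff(panel$snp_id, names(cohort))
  if (length(missing_snps)) {
    stop("panel SNPs absent from cohort: ", paste(missing_snps, collapse = ", "))
  }
  d <- as.matrix(cohort[, panel$snp_id, drop = FALSE])
  if (anyNA(d)) {
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- 2 * panel$effect_allele_freq[j]
    }
  }
  scores <- as.vector(d %*% panel$log_or)
  names(scores) <- cohort$sample_id
  scores
}

#' Theoretical normal model of the PRS distribution
#'
#' Under a multiplicative (log-additive) polygenic model with many unlinked
#' loci each of small effect, the population distribution of the PRS is
#' normal, \eqn{F = N(\mu, \sigma^2)}, with
#' \deqn{\mu = 2 \sum_i p_i \beta_i, \qquad
#'       \sigma^2 = 2 \sum_i p_i q_i \beta_i^2,}
#' where \eqn{q_i = 1 - p_i}; these are exactly the mean and variance of a
#' sum of independent Binomial(2, \eqn{p_i}) dosages weighted by
#' \eqn{\beta_i}. For a rare disease, the score distribution among cases is
#' the exponentially tilted density \eqn{g(r) \propto e^r f(r)}, which for
#' a normal \eqn{f} is again normal with the same variance and mean shifted
#' by the variance: \eqn{G = N(\mu + \sigma^2, \sigma^2)}. That mean shift
#' is what makes every discrimination metric a closed form in \eqn{\sigma}
#' alone.
#'
#' @param panel a [snp_panel()] of selected, weighted SNPs.
#' @return Object of class `prs_model`: list with `panel`, `n_snps`, `mu`,
#'   `sigma2`, `sigma`, `mu_case`.
#' @seealso [population_density()], [stratify()], [analytic_auc()]
#' @export
#' @examples
#' prs_model(snp_panel("rs1", "l1", "A", 0.5, log(2)))
prs_model <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  p <- panel$effect_allele_freq
  q <- 1 - p
  beta <- panel$log_or
  mu <- 2 * sum(p * beta)
  sigma2 <- 2 * sum(p * q * beta^2)
  structure(list(panel = panel, n_snps = nrow(panel), mu = mu,
                 sigma2 = sigma2, sigma = sqrt(sigma2),
                 mu_case = mu + sigma2),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat("Normal polygenic score model (", x$n_snps, " SNPs)\n", sep = "")
  cat(sprintf("  population: N(mu = %.4f, sd = %.4f)\n", x$mu, x$sigma))
  cat(sprintf("  cases:      N(mu + sigma^2 = %.4f, sd = %.4f)\n",
              x$mu_case, x$sigma))
  invisible(x)
}

#' Model densities of the PRS in the population and in cases
#'
#' Normal densities of the fitted score model: `population_density()` is
#' \eqn{N(\mu, \sigma^2)}, `case_density()` is
#' \eqn{N(\mu + \sigma^2, \sigma^2)}. The two satisfy the Gaussian tilt
#' identity \eqn{g(r)/f(r) \propto e^r}.
#'
#' @param model a [prs_model()] with `sigma2 > 0`.
#' @param score numeric vector of score values.
#' @return Density values.
#' @export
population_density <- function(model, score) {
  stopifnot(inherits(model, "prs_model"))
  if (model$sigma2 <= 0) stop("degenerate model: sigma2 = 0")
  stats::dnorm(score, model$mu, model$sigma)
}

#' @rdname population_density
#' @export
case_density <- function(model, score) {
  stopifnot(inherits(model, "prs_model"))
  if (model$sigma2 <= 0) stop("degenerate model: sigma2 = 0")
  stats::dnorm(score, model$mu_case, model$sigma)
}
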