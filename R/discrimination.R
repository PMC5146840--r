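#' Case share of a PRS percentile interval
#'
#' Proportion of all cases whose score falls between the population
#' percentiles `u` and `v` of the PRS, under the normal score model with
#' standard deviation `sigma`:
#' \deqn{\Phi(\Phi^{-1}(1-u) + \sigma) - \Phi(\Phi^{-1}(1-v) + \sigma).}
#' The endpoints 0 and 1 are handled as limits (\eqn{\Phi^{-1}(0) =
#' -\infty}, \eqn{\Phi^{-1}(1) = +\infty}).
#'
#' @param u,v population percentiles, `0 <= u < v <= 1` (vectorized).
#' @param sigma PRS standard deviation, `>= 0`.
#' @return Case shares in \[0, 1\].
#' @export
case_share <- function(u, v, sigma) {
  check_intervals(u, v)
  stopifnot(sigma >= 0)
  stats::pnorm(stats::qnorm(1 - u) + sigma) -
    stats::pnorm(stats::qnorm(1 - v) + sigma)
}

check_intervals <- function(u, v) {
  if (any(u < 0) || any(v > 1) || any(u >= v)) {
    stop("percentile intervals must satisfy 0 <= u < v <= 1")
  }
}

#' Predicted odds ratio of a PRS percentile interval
#'
#' Theoretical odds ratio of disease for individuals in the score interval
#' between population percentiles (`u`, `v`), relative to the middle
#' quintile (40th-60th percentiles), under the normal score model:
#' \deqn{OR_{(u,v)} = \frac{(0.6-0.4)\,[\Phi(\Phi^{-1}(1-u)+\sigma) -
#'   \Phi(\Phi^{-1}(1-v)+\sigma)]}{(v-u)\,[\Phi(\Phi^{-1}(0.6)+\sigma) -
#'   \Phi(\Phi^{-1}(0.4)+\sigma)]},}
#' i.e. the ratio of case-to-population share in the interval over the same
#' ratio in the reference band. `sigma = 0` gives 1 for every interval.
#'
#' @inheritParams case_share
#' @return Odds ratios (vectorized over `u`, `v`).
#' @export
#' @examples
#' predicted_or(0.99, 1, sigma = 0.38)  # top 1% vs middle quintile: 2.77
#' predicted_or(0, 0.01, sigma = 0.38)  # bottom 1%: 0.37
predicted_or <- function(u, v, sigma) {
  ref <- case_share(0.4, 0.6, sigma) / 0.2
  (case_share(u, v, sigma) / (v - u)) / ref
}

#' Analytic area under the ROC curve of the PRS
#'
#' The AUC is \eqn{\int (1 - G(r))\, dF(r)}, the probability that a random
#' case outscores a random non-case, with \eqn{F = N(\mu, \sigma^2)} the
#' population and \eqn{G = N(\mu+\sigma^2, \sigma^2)} the case score
#' distribution. Evaluated by adaptive quadrature; for this equal-variance
#' binormal pair the integral equals \eqn{\Phi(\sigma/\sqrt{2})}, which the
#' test suite uses as an independent check of the quadrature.
#'
#' @param sigma PRS standard deviation, `>= 0`.
#' @return AUC in \[0.5, 1\).
#' @export
#' @examples
#' analytic_auc(0.38)  # 0.606
analytic_auc <- function(sigma) {
  stopifnot(length(sigma) == 1, sigma >= 0)
  if (sigma == 0) return(0.5)
  # location-invariant: take mu = 0
  stats::integrate(function(r) {
    (1 - stats::pnorm(r, sigma^2, sigma)) * stats::dnorm(r, 0, sigma)
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Empirical (nonparametric) AUC
#'
#' Mann-Whitney concordance probability: the proportion of case-control
#' score pairs in which the case scores higher, ties counted one half.
#' Computed from midranks in \eqn{O(n \log n)}.
#'
#' @param scores numeric score vector.
#' @param status 0/1 case indicator aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(scores, status) {
  stopifnot(length(scores) == length(status), all(status %in% c(0, 1)))
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both cases and controls are required")
  r <- rank(scores)  # midranks handle ties
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Proportion of cases followed (PCF)
#'
#' The fraction of all cases found among the proportion `q` of the
#' population at highest PRS: \eqn{PCF(q) = \Phi(\Phi^{-1}(q) + \sigma)}.
#' Equivalently, the case share of the top-`q` score stratum, so
#' `pcf(q, sigma) >= q`, with equality iff `sigma = 0`.
#'
#' @param q proportion of the population followed, in \[0, 1\] (vectorized).
#' @param sigma PRS standard deviation, `>= 0`.
#' @return Proportions of cases captured.
#' @seealso [pnf()] for the inverse.
#' @export
#' @examples
#' pcf(0.01, 0.38)  # 2.6% of cases in the top 1% of scores
#' pcf(0.30, 0.38)  # 44.3% in the top 30%
pcf <- function(q, sigma) {
  stopifnot(all(q >= 0 & q <= 1), sigma >= 0)
  stats::pnorm(stats::qnorm(q) + sigma)
}

#' Proportion needed to follow (PNF)
#'
#' The fraction of the population, taken from the top of the score
#' distribution, that must be followed to capture a proportion `p` of all
#' cases: \eqn{PNF(p) = \Phi(\Phi^{-1}(p) - \sigma)}, the inverse of
#' [pcf()] in `q`.
#'
#' @param p proportion of cases to capture, in (0, 1) (vectorized).
#' @param sigma PRS standard deviation, `>= 0`.
#' @return Population fractions.
#' @export
#' @examples
#' pnf(0.80, 0.38)  # screen 67.8% of women to catch 80% of cases
pnf <- function(p, sigma) {
  stopifnot(all(p > 0 & p < 1), sigma >= 0)
  stats::pnorm(stats::qnorm(p) - sigma)
}

#' Population attributable risk of the score distribution
#'
#' The fraction of disease incidence attributable to the spread of the PRS
#' relative to the 40th-60th percentile reference band:
#' \deqn{PAR = 1 - \sum_j \frac{A_j}{OR_j},}
#' where the sum runs over a partition of (0, 1) into percentile intervals,
#' \eqn{A_j} is the case share of interval `j` ([case_share()]) and
#' \eqn{OR_j} its predicted odds ratio ([predicted_or()]). Used to deflate
#' the population incidence to the reference-band baseline hazard,
#' \eqn{h_1(t) = h^*(t)(1 - PAR)}.
#'
#' @param sigma PRS standard deviation, `>= 0`.
#' @param breaks increasing percentile breakpoints starting at 0 and ending
#'   at 1; consecutive pairs form the partition. The default is the decile
#'   partition with the 40-60 reference band merged.
#' @return PAR in \[0, 1).
#' @export
#' @examples
#' polygenic_par(sigma = 0.38)  # 0.068
polygenic_par <- function(sigma, breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.6,
                                            0.7, 0.8, 0.9, 1)) {
  stopifnot(sigma >= 0)
  check_breaks(breaks, full = TRUE)
  u <- breaks[-length(breaks)]
  v <- breaks[-1]
  1 - sum(case_share(u, v, sigma) / predicted_or(u, v, sigma))
}

check_breaks <- function(breaks, full = FALSE) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  if (any(breaks < 0) || any(breaks > 1)) stop("breaks must lie in [0, 1]")
  if (full && (breaks[1] != 0 || breaks[length(breaks)] != 1)) {
    stop("partition must cover (0, 1): breaks must start at 0 and end at 1")
  }
}

#' Canonical PRS percentile bands for reporting
#'
#' The band layout used in the package's stratification tables: the decile
#' bands with the 40-60 reference merged (a partition of (0,1)), plus, for
#' `type = "display"`, the two 1% tail bands (0-1 and 99-100) that are
#' conventionally reported alongside.
#'
#' @param type `"partition"` (nine non-overlapping bands) or `"display"`
#'   (eleven bands including the overlapping 1% tails).
#' @return Data frame with columns `u`, `v`.
#' @export
percentile_bands <- function(type = c("partition", "display")) {
  type <- match.arg(type)
  breaks <- c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9, 1)
  bands <- data.frame(u = breaks[-length(breaks)], v = breaks[-1])
  if (type == "display") {
    bands <- rbind(data.frame(u = 0, v = 0.01), bands,
                   data.frame(u = 0.99, v = 1))
    bands <- bands[order(bands$u, bands$v), , drop = FALSE]
    rownames(bands) <- NULL
  }
  bands
}

#' Stratify risk by PRS percentile
#'
#' Builds the full risk-stratification summary for a score model: one row
#' per percentile interval with its population share, case share and
#' predicted odds ratio versus the 40-60 band, plus the overall analytic
#' AUC and the PAR of the partition.
#'
#' @param sigma PRS standard deviation (e.g. `prs_model(panel)$sigma`).
#' @param breaks increasing percentile breakpoints in \[0, 1\] defining the
#'   partition; default as in [polygenic_par()].
#' @param bands optional data frame of extra display intervals (columns
#'   `u`, `v`), e.g. `percentile_bands("display")`, reported instead of the
#'   partition rows; PAR and case-share accounting always use `breaks`.
#' @return Object of class `prs_stratification`: list with `intervals`
#'   (data frame `u`, `v`, `pop_share`, `case_share`, `predicted_or`),
#'   `par`, `auc`, `sigma`, `reference`.
#' @export
#' @examples
#' stratify(sigma = 0.38)
stratify <- function(sigma, breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.6,
                                       0.7, 0.8, 0.9, 1),
                     bands = NULL) {
  stopifnot(sigma >= 0)
  check_breaks(breaks, full = TRUE)
  if (is.null(bands)) {
    bands <- data.frame(u = breaks[-length(breaks)], v = breaks[-1])
  }
  intervals <- data.frame(
    u = bands$u, v = bands$v,
    pop_share = bands$v - bands$u,
    case_share = case_share(bands$u, bands$v, sigma),
    predicted_or = predicted_or(bands$u, bands$v, sigma)
  )
  structure(list(intervals = intervals,
                 par = polygenic_par(sigma, breaks),
                 auc = analytic_auc(sigma),
                 sigma = sigma,
                 reference = c(0.4, 0.6)),
            class = "prs_stratification")
}

#' @export
print.prs_stratification <- function(x, digits = 3, ...) {
  cat(sprintf("PRS risk stratification (sigma = %.3g)\n", x$sigma))
  iv <- x$intervals
  tab <- data.frame(
    `PRS percentile` = sprintf("%g-%g", 100 * iv$u, 100 * iv$v),
    `predicted OR` = round(iv$predicted_or, digits),
    `population share` = round(iv$pop_share, digits),
    `case share` = round(iv$case_share, digits),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  cat(sprintf("AUC = %.3f   PAR = %.1f%%   (reference band %g-%g)\n",
              x$auc, 100 * x$par, 100 * x$reference[1], 100 * x$reference[2]))
  invisible(x)
}
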