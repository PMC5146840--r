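#' Per-SNP log-additive logistic association
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood
#' ([stats::glm()] with a binomial link, i.e. iteratively reweighted least
#' squares; convergence tolerance 1e-8, at most 100 iterations). The dosage
#' enters as a single linear term, the log-additive genetic model. The
#' one-sided p-value is taken in the direction of the panel's a-priori
#' risk allele: with `direction = sign(reported log OR)`, the signed
#' statistic is `z = direction * beta_hat / se` and `p = P(Z >= z)`, so
#' small p means the data support the previously reported direction.
#'
#' Monomorphic SNPs, non-converged fits, and (quasi-)separated fits are
#' returned flagged rather than failing; flagged results are excluded from
#' meta-analysis with a warning.
#'
#' @param cohort a [cohort_table()] containing both cases and controls
#'   (typically one study's subset).
#' @param snp_id name of the dosage column to test.
#' @param covariates character vector of adjustment columns (default
#'   `"age"`); `"study"` is added automatically by [run_association()]
#'   when a subset spans several studies.
#' @param direction +1 or -1, the a-priori risk-allele direction
#'   (default +1: the effect allele is the risk allele).
#' @return One-row data frame: `snp_id`, `study`, `log_or_hat`, `se`, `z`,
#'   `p_one_sided`, `n_cases`, `n_controls`, `flag` (`NA` when clean).
#' @export
fit_snp <- function(cohort, snp_id, covariates = "age", direction = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!snp_id %in% names(cohort)) stop("no dosage column '", snp_id, "'")
  if (length(unique(cohort$status)) < 2) {
    stop("cohort must contain both cases and controls")
  }
  direction <- if (direction < 0) -1 else 1
  study_label <- if (length(unique(cohort$study)) == 1)
    as.character(cohort$study[1]) else "pooled"
  out <- data.frame(snp_id = snp_id, study = study_label,
                    log_or_hat = NA_real_, se = NA_real_, z = NA_real_,
                    p_one_sided = NA_real_,
                    n_cases = sum(cohort$status == 1),
                    n_controls = sum(cohort$status == 0),
                    flag = NA_character_, stringsAsFactors = FALSE)
  dose <- cohort[[snp_id]]
  if (stats::var(dose, na.rm = TRUE) == 0 || all(is.na(dose))) {
    out$flag <- "monomorphic"
    return(out)
  }
  dat <- data.frame(status = cohort$status, dosage = dose)
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  # drop covariates with a single level (e.g. study within one study)
  keep <- vapply(covariates, function(cv) length(unique(dat[[cv]])) > 1,
                 logical(1))
  form <- stats::reformulate(c("dosage", covariates[keep]), response = "status")
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  est <- stats::coef(fit)["dosage"]
  se <- sqrt(diag(stats::vcov(fit)))["dosage"]
  if (!fit$converged) {
    out$flag <- "nonconverged"
  } else if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 100) {
    out$flag <- "separation"
  } else {
    out$log_or_hat <- unname(est)
    out$se <- unname(se)
    out$z <- direction * out$log_or_hat / out$se
    out$p_one_sided <- stats::pnorm(out$z, lower.tail = FALSE)
  }
  out
}

#' Run per-study association fits for a whole panel
#'
#' Applies [fit_snp()] to every panel SNP within every study of the cohort,
#' taking the risk-allele direction for the one-sided test from the sign of
#' the panel's reported log odds ratio.
#'
#' @param cohort a [cohort_table()].
#' @param panel a [snp_panel()]; each `snp_id` must be a dosage column.
#' @param covariates adjustment columns passed to [fit_snp()].
#' @return Data frame of class `assoc_results`, one row per study x SNP.
#' @export
run_association <- function(cohort, panel, covariates = "age") {
  stopifnot(inherits(cohort, "cohort_table"), inherits(panel, "snp_panel"))
  missing_snps <- setdiff(panel$snp_id, names(cohort))
  if (length(missing_snps)) {
    stop("panel SNPs absent from cohort: ", paste(missing_snps, collapse = ", "))
  }
  studies <- unique(as.character(cohort$study))
  rows <- lapply(studies, function(st) {
    sub <- cohort[cohort$study == st, , drop = FALSE]
    class(sub) <- class(cohort)
    do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      fit_snp(sub, panel$snp_id[i], covariates = covariates,
              direction = sign_or_one(panel$log_or[i]))
    }))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("assoc_results", "data.frame")
  res
}

sign_or_one <- function(x) if (x < 0) -1 else 1

#' Fixed-effect inverse-variance meta-analysis of one SNP
#'
#' Pools per-study log odds ratios with weights \eqn{w_k = 1/se_k^2}:
#' the pooled estimate is \eqn{\sum w_k \hat\beta_k / \sum w_k} and the
#' pooled standard error \eqn{(\sum w_k)^{-1/2}}. Cochran's Q
#' (\eqn{\sum w_k (\hat\beta_k - \hat\beta_{pool})^2}, chi-square on
#' \eqn{k-1} df) quantifies between-study heterogeneity; it is reported,
#' not used for exclusion.
#'
#' @param log_or per-study estimates.
#' @param se per-study standard errors (positive).
#' @param direction a-priori risk-allele direction for the one-sided p.
#' @return List: `pooled_log_or`, `pooled_se`, `z`, `p_one_sided`,
#'   `heterogeneity_Q`, `heterogeneity_df`, `heterogeneity_p`, `k`.
#' @export
#' @examples
#' meta_fixed(c(0.10, 0.20), c(0.05, 0.05))  # equal se: plain mean, se/sqrt(2)
meta_fixed <- function(log_or, se, direction = 1) {
  ok <- is.finite(log_or) & is.finite(se) & se > 0
  log_or <- log_or[ok]; se <- se[ok]
  if (!length(log_or)) stop("no usable study estimates to pool")
  direction <- if (direction < 0) -1 else 1
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  k <- length(log_or)
  Q <- sum(w * (log_or - pooled)^2)
  z <- direction * pooled / pooled_se
  list(pooled_log_or = pooled, pooled_se = pooled_se, z = z,
       p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       heterogeneity_Q = Q, heterogeneity_df = k - 1L,
       heterogeneity_p = if (k > 1)
         stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_,
       k = k)
}

#' Meta-analyse per-study association results across a panel
#'
#' Pools the unflagged per-study estimates of each SNP with [meta_fixed()].
#' SNPs whose fits were all flagged are dropped with a warning.
#'
#' @param assoc an `assoc_results` frame from [run_association()].
#' @param panel the [snp_panel()] that defined the tests (supplies the
#'   risk-allele direction).
#' @return Data frame of class `meta_results`, one row per SNP:
#'   `snp_id`, `pooled_log_or`, `pooled_se`, `z`, `p_one_sided`,
#'   `heterogeneity_Q`, `heterogeneity_df`, `heterogeneity_p`, `k`.
#' @export
run_meta <- function(assoc, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  flagged <- assoc[!is.na(assoc$flag), ]
  if (nrow(flagged)) {
    warning(nrow(flagged), " flagged per-study fit(s) excluded from pooling (",
            paste(unique(flagged$flag), collapse = ", "), ")")
  }
  rows <- lapply(panel$snp_id, function(id) {
    sub <- assoc[assoc$snp_id == id & is.na(assoc$flag), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    m <- meta_fixed(sub$log_or_hat, sub$se,
                    direction = sign_or_one(panel$log_or[panel$snp_id == id]))
    data.frame(snp_id = id, pooled_log_or = m$pooled_log_or,
               pooled_se = m$pooled_se, z = m$z,
               p_one_sided = m$p_one_sided,
               heterogeneity_Q = m$heterogeneity_Q,
               heterogeneity_df = m$heterogeneity_df,
               heterogeneity_p = m$heterogeneity_p, k = m$k,
               stringsAsFactors = FALSE)
  })
  dropped <- panel$snp_id[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("SNP(s) with no usable study fit dropped: ",
            paste(dropped, collapse = ", "))
  }
  res <- do.call(rbind, rows)
  class(res) <- c("meta_results", "data.frame")
  res
}

#' Replication filtering and best-SNP-per-locus selection
#'
#' Retains SNPs whose one-sided meta-analysis p-value is below `alpha`
#' (replication in the previously reported direction), then keeps only the
#' most significant SNP within each locus (ties broken by lexicographically
#' smallest `snp_id`, so selection is deterministic). The returned panel
#' carries the pooled log odds ratios as the score weights by default;
#' `weights = "panel"` keeps the externally reported weights instead.
#'
#' @param meta a `meta_results` frame from [run_meta()].
#' @param panel the candidate [snp_panel()].
#' @param alpha one-sided significance threshold (default 0.05).
#' @param weights `"pooled"` (re-estimated weights, default) or `"panel"`.
#' @return A [snp_panel()] of the selected SNPs.
#' @export
select_snps <- function(meta, panel, alpha = 0.05,
                        weights = c("pooled", "panel")) {
  weights <- match.arg(weights)
  stopifnot(inherits(panel, "snp_panel"))
  if (!all(meta$snp_id %in% panel$snp_id)) {
    stop("meta results contain SNPs not in the panel")
  }
  hit <- meta[meta$p_one_sided < alpha, , drop = FALSE]
  if (!nrow(hit)) return(panel[0, , drop = FALSE])
  hit$locus_id <- panel$locus_id[match(hit$snp_id, panel$snp_id)]
  hit <- hit[order(hit$locus_id, hit$p_one_sided, hit$snp_id), , drop = FALSE]
  best <- hit[!duplicated(hit$locus_id), , drop = FALSE]
  sel <- panel[match(best$snp_id, panel$snp_id), , drop = FALSE]
  if (weights == "pooled") sel$log_or <- best$pooled_log_or
  rownames(sel) <- NULL
  validate_snp_panel(sel)
}
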