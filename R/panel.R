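#' Construct a SNP weight panel
#'
#' A SNP panel holds the per-SNP weights of a polygenic risk score (PRS):
#' for each variant, its identifier, the locus it belongs to, the effect
#' (risk) allele, the effect-allele frequency \eqn{p_i} in the target
#' population, and the per-allele log odds ratio \eqn{\beta_i}. The PRS of
#' an individual is \eqn{\sum_i \beta_i x_i} where \eqn{x_i} is the
#' effect-allele dosage (0, 1 or 2; fractional for imputed genotypes).
#'
#' @param snp_id character vector of unique variant identifiers.
#' @param locus_id character vector assigning each SNP to a locus; several
#'   SNPs may share a locus (only one per locus survives selection, see
#'   [select_snps()]).
#' @param effect_allele character vector, the allele counted by the dosage.
#' @param effect_allele_freq numeric in (0, 1), frequency of the effect
#'   allele.
#' @param log_or numeric, finite per-allele log odds ratio.
#'
#' @return A data frame of class `snp_panel` with one row per SNP.
#' @seealso [read_snp_panel()], [prs_model()], [compute_prs()]
#' @export
#' @examples
#' snp_panel("rs1", "locus1", "A", 0.25, log(1.2))
snp_panel <- function(snp_id, locus_id, effect_allele,
                      effect_allele_freq, log_or) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    locus_id = as.character(locus_id),
    effect_allele = as.character(effect_allele),
    effect_allele_freq = as.numeric(effect_allele_freq),
    log_or = as.numeric(log_or),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicated snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  }
  if (any(!is.finite(panel$effect_allele_freq)) ||
      any(panel$effect_allele_freq <= 0) ||
      any(panel$effect_allele_freq >= 1)) {
    stop("effect_allele_freq must lie strictly in (0, 1)")
  }
  if (any(!is.finite(panel$log_or))) stop("log_or must be finite")
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Read or write a SNP panel as tab-separated text
#'
#' The on-disk format is TSV with header columns `snp_id`, `locus_id`,
#' `effect_allele`, `effect_allele_freq`, `log_or`.
#'
#' @param path file path.
#' @return `read_snp_panel()` returns a validated [snp_panel()];
#'   `write_snp_panel()` returns `path` invisibly.
#' @export
read_snp_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "locus_id", "effect_allele", "effect_allele_freq", "log_or")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("panel file lacks columns: ", paste(miss, collapse = ", "))
  validate_snp_panel(x[need])
}

#' @rdname read_snp_panel
#' @param panel a [snp_panel()].
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a case-control cohort table
#'
#' A cohort table is the unit of association analysis: one row per
#' individual with `sample_id`, `study` label, case `status` (0 control /
#' 1 case), an `age` covariate, and one dosage column per SNP (named by
#' `snp_id`, values in \[0, 2\]; fractional dosages from imputation are
#' accepted, `NA` allowed).
#'
#' @param x data frame with the columns above.
#' @return A data frame of class `cohort_table`.
#' @seealso [generate_cohort()], [compute_prs()], [fit_snp()]
#' @export
cohort_table <- function(x) {
  need <- c("sample_id", "study", "status", "age")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (!all(x$status %in% c(0L, 1L))) stop("status must be 0 (control) or 1 (case)")
  snp_cols <- setdiff(names(x), need)
  for (s in snp_cols) {
    d <- x[[s]]
    if (!is.numeric(d)) stop("dosage column '", s, "' is not numeric")
    if (any(d < 0 | d > 2, na.rm = TRUE)) {
      stop("dosages in '", s, "' outside [0, 2]")
    }
  }
  attr(x, "snp_cols") <- snp_cols
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Read or write a cohort table as tab-separated text
#'
#' TSV with header `sample_id`, `study`, `status`, `age`, then one dosage
#' column per SNP.
#'
#' @param path file path.
#' @return `read_cohort()` returns a validated [cohort_table()];
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(x)
}

#' @rdname read_cohort
#' @param cohort a [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an age-specific rate table
#'
#' Holds the hazards that drive absolute-risk projection: disease incidence
#' \eqn{h^*(t)} and competing (all-cause-minus-disease) mortality
#' \eqn{h_2(t)}, both per person-year, on contiguous half-open age bands
#' \eqn{[start, end)}.
#'
#' @param age_start,age_end numeric vectors of band boundaries in years;
#'   bands must be contiguous and non-overlapping.
#' @param incidence,mortality non-negative hazards per person-year.
#' @return A data frame of class `rate_table`.
#' @seealso [generate_rate_table()], [absolute_risk()]
#' @export
#' @examples
#' rate_table(c(20, 50), c(50, 80), c(2e-4, 7e-4), c(1e-3, 8e-3))
rate_table <- function(age_start, age_end, incidence, mortality) {
  rt <- data.frame(age_start = as.numeric(age_start),
                   age_end = as.numeric(age_end),
                   incidence = as.numeric(incidence),
                   mortality = as.numeric(mortality))
  o <- order(rt$age_start)
  rt <- rt[o, , drop = FALSE]
  rownames(rt) <- NULL
  if (any(rt$age_end <= rt$age_start)) stop("age bands must have positive width")
  if (nrow(rt) > 1 &&
      any(abs(rt$age_start[-1] - rt$age_end[-nrow(rt)]) > 1e-9)) {
    stop("age bands must be contiguous and non-overlapping")
  }
  if (any(rt$incidence < 0) || any(rt$mortality < 0)) {
    stop("hazards must be non-negative")
  }
  class(rt) <- c("rate_table", "data.frame")
  rt
}

#' Read or write a rate table as comma-separated text
#'
#' CSV with header `age_start`, `age_end`, `incidence_per_100k`,
#' `mortality_per_100k` (rates per 100,000 person-years, the scale on
#' which registries publish them); converted to per-person-year hazards
#' on read.
#'
#' @param path file path.
#' @return `read_rate_table()` returns a [rate_table()];
#'   `write_rate_table()` returns `path` invisibly.
#' @export
read_rate_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "age_end", "incidence_per_100k", "mortality_per_100k")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("rate table lacks columns: ", paste(miss, collapse = ", "))
  rate_table(x$age_start, x$age_end,
             x$incidence_per_100k / 1e5, x$mortality_per_100k / 1e5)
}

#' @rdname read_rate_table
#' @param rates a [rate_table()].
#' @export
write_rate_table <- function(rates, path) {
  out <- data.frame(age_start = rates$age_start, age_end = rates$age_end,
                    incidence_per_100k = rates$incidence * 1e5,
                    mortality_per_100k = rates$mortality * 1e5)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
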