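#' Run the full risk-stratification pipeline
#'
#' End-to-end driver: simulate (or load) a multi-study case-control
#' dataset, run per-SNP association and fixed-effect meta-analysis, filter
#' and select one SNP per locus, compute scores and the normal score model,
#' derive the stratification table (predicted interval ORs, AUC, PCF/PNF,
#' PAR), and -- when a rate table is available -- project absolute risks.
#' Alternatively, with a `sigma` override and no data, only the analytic
#' stages run: every discrimination quantity is a closed form in `sigma`.
#'
#' The pipeline is a pure function of its arguments: a fixed `seed` (used
#' by the simulator) makes repeated runs byte-identical, including all
#' artifacts written to `out_dir`.
#'
#' @param sigma optional PRS standard deviation; mutually exclusive with
#'   `sim`. When given, the data stages are skipped.
#' @param sim optional [sim_config()] describing the synthetic dataset;
#'   its `seed` governs all randomness.
#' @param panel,cohort optional pre-built [snp_panel()] / [cohort_table()]
#'   (e.g. read from disk) used instead of simulation when `sim` is `NULL`.
#' @param rates optional [rate_table()]; enables the absolute-risk stage.
#' @param alpha one-sided replication threshold (default 0.05).
#' @param breaks percentile partition for PAR and the stratification table.
#' @param pnf_grid PNF values tabulated in the screening-yield table.
#' @param weights weight source after selection, `"pooled"` or `"panel"`.
#' @param covariates adjustment covariates for the association fits.
#' @param out_dir optional directory; when given, every intermediate
#'   artifact is written there as delimited text.
#' @return Object of class `prs_report`: list with (depending on inputs)
#'   `panel`, `cohort_n`, `assoc`, `meta`, `selected`, `model`, `scores`,
#'   `empirical_auc`, `sigma`, `stratification`, `pcf_table`, `risks`.
#' @export
#' @examples
#' rep <- run_pipeline(sigma = 0.38)
#' rep$stratification
run_pipeline <- function(sigma = NULL, sim = NULL, panel = NULL,
                         cohort = NULL, rates = NULL, alpha = 0.05,
                         breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.7,
                                    0.8, 0.9, 1),
                         pnf_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                      0.6, 0.7, 0.8, 0.9, 0.95, 0.99),
                         weights = "pooled", covariates = "age",
                         out_dir = NULL) {
  if (!is.null(sigma) && (!is.null(sim) || !is.null(cohort))) {
    stop("sigma override and data inputs are mutually exclusive")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, file, write_fun = NULL) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    if (is.null(write_fun)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      write_fun(x, path)
    }
  }
  report <- list()

  if (is.null(sigma)) {
    if (!is.null(sim)) {
      message("stage simulate: ", sim$n_snps, " SNPs, ",
              sum(sim$studies$n_cases), " cases / ",
              sum(sim$studies$n_controls), " controls")
      panel <- generate_panel(sim)
      cohort <- generate_cohort(panel, sim)
    }
    if (is.null(panel) || is.null(cohort)) {
      stop("need either sigma, a sim config, or a panel plus cohort")
    }
    emit(panel, "panel.tsv", write_snp_panel)
    emit(cohort, "cohort.tsv", write_cohort)
    report$panel <- panel
    report$cohort_n <- nrow(cohort)

    message("stage assoc: per-study logistic fits + fixed-effect meta-analysis")
    assoc <- run_association(cohort, panel, covariates = covariates)
    meta <- run_meta(assoc, panel)
    emit(assoc, "association.tsv")
    emit(meta, "meta.tsv")
    report$assoc <- assoc
    report$meta <- meta

    message("stage select: one-sided alpha = ", alpha, ", best SNP per locus")
    selected <- select_snps(meta, panel, alpha = alpha, weights = weights)
    if (nrow(selected) == 0) stop("stage select: no SNP passed replication")
    emit(selected, "selected_panel.tsv", write_snp_panel)
    report$selected <- selected

    message("stage prs: scoring ", nrow(cohort), " individuals with ",
            nrow(selected), " SNPs")
    model <- prs_model(selected)
    scores <- compute_prs(cohort, selected)
    emit(data.frame(sample_id = names(scores), status = cohort$status,
                    prs = scores), "scores.tsv")
    report$model <- model
    report$scores <- scores
    report$empirical_auc <- empirical_auc(scores, cohort$status)
    sigma <- model$sigma
  }
  report$sigma <- sigma

  message("stage discriminate: sigma = ", signif(sigma, 4))
  strat <- stratify(sigma, breaks = breaks,
                    bands = percentile_bands("display"))
  pcf_table <- data.frame(pnf = pnf_grid, pcf = pcf(pnf_grid, sigma))
  emit(cbind(strat$intervals,
             auc = strat$auc, par = strat$par), "stratification.tsv")
  emit(pcf_table, "pcf_table.tsv")
  report$stratification <- strat
  report$pcf_table <- pcf_table

  if (!is.null(rates)) {
    message("stage absrisk: lifetime (20-80) and 10-year (50-60) projections")
    lifetime <- risk_table(rates, strat, alpha = 20, tau = 60)
    tenyear <- risk_table(rates, strat, alpha = 50, tau = 10)
    risks <- data.frame(lifetime[, c("u", "v", "predicted_or")],
                        lifetime_risk = lifetime$risk,
                        ten_year_risk = tenyear$risk)
    emit(risks, "risk_table.tsv")
    report$risks <- risks
  }
  class(report) <- "prs_report"
  if (!is.null(out_dir)) {
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
  }
  report
}

format_report <- function(x) {
  strat <- x$stratification
  iv <- strat$intervals
  c(sprintf("PRS risk stratification report"),
    if (!is.null(x$selected))
      sprintf("selected SNPs: %d of %d candidates", nrow(x$selected),
              nrow(x$panel)),
    if (!is.null(x$cohort_n)) sprintf("individuals scored: %d", x$cohort_n),
    sprintf("sigma = %.4f   analytic AUC = %.3f   PAR = %.1f%%",
            x$sigma, strat$auc, 100 * strat$par),
    if (!is.null(x$empirical_auc))
      sprintf("empirical AUC = %.3f", x$empirical_auc),
    "",
    "band\tpredicted_or\tpop_share\tcase_share",
    sprintf("%g-%g\t%.2f\t%.3f\t%.3f", 100 * iv$u, 100 * iv$v,
            iv$predicted_or, iv$pop_share, iv$case_share),
    "",
    "pnf\tpcf",
    sprintf("%.2f\t%.3f", x$pcf_table$pnf, x$pcf_table$pcf))
}

#' @export
print.prs_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
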