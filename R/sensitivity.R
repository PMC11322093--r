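# Sensitivity battery: heterogeneity, pleiotropy, outliers, leave-one-out,
# Steiger retention, and reverse MR, summarized as machine-readable flags.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` over per-SNP Wald ratios with IVW
#' weights `w_j = gamma_j^2 / sigma_Gamma_j^2`; equals the weighted residual
#' sum of squares of the IVW through-origin fit. Excess heterogeneity across
#' instruments is indicative of pleiotropy. p from the chi-squared
#' distribution on n-1 degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(x) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 2, "Cochran's Q")
  est <- mr_ivw(rows)
  list(Q = est$extras$Q, df = est$extras$Q_df, pval = est$extras$Q_pval)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate n times, each time omitting one SNP; the
#' single-SNP-driver flag is set when the full-set IVW is significant at
#' `alpha` but at least one leave-one-out estimate is not, i.e. when the
#' result hinges on a single instrument.
#'
#' @inheritParams mr_ivw
#' @param alpha significance level for the driver flag (default 0.05).
#' @return list with `estimates` (data frame: `left_out`, `beta`, `se`,
#'   `pval`) and `driver_flag`.
#' @export
leave_one_out <- function(x, alpha = 0.05) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "leave-one-out")
  full <- mr_ivw(rows)
  res <- lapply(seq_len(n), function(j) {
    e <- mr_ivw(rows[-j, , drop = FALSE])
    data.frame(left_out = if ("snp_id" %in% names(rows)) rows$snp_id[j] else
                 as.character(j),
               beta = e$beta, se = e$se, pval = e$pval,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  driver <- full$pval < alpha && any(res$pval >= alpha)
  list(estimates = res, driver_flag = driver, full = full)
}

#' Reverse MR
#'
#' Swaps the roles of exposure and outcome, reruns the full instrument
#' cascade and IVW. A significant reverse estimate suggests the nominal
#' outcome causally influences the nominal exposure.
#'
#' @param exposure,outcome [summary_stats] objects in their *forward* roles.
#' @param panel an [ld_panel].
#' @param config an [instrument_config()].
#' @return list with `evaluable` (logical), `estimate` (reverse IVW
#'   [mr_estimate][new_mr_estimate] or `NULL`), and `n_snp`.
#' @export
reverse_mr <- function(exposure, outcome, panel,
                       config = instrument_config()) {
  iset <- tryCatch(
    build_instrument_set(outcome, exposure, panel, config),
    netmr_empty_selection = function(e) NULL)
  if (is.null(iset) || nrow(iset$harmonized$rows) < 2) {
    return(list(evaluable = FALSE, estimate = NULL, n_snp = 0L))
  }
  est <- mr_ivw(iset)
  list(evaluable = TRUE, estimate = est, n_snp = est$n_snp)
}

#' Derive sensitivity flags from stored statistics
#'
#' Pure function of the statistics and `alpha`, so reports can be re-flagged
#' under a different level. Conventions: heterogeneity flagged when the Q
#' test is significant; pleiotropy when either the Egger intercept or the
#' MR-PRESSO global test is significant; outliers when MR-PRESSO flagged
#' SNPs *and* the corrected estimate disagrees with the raw one in sign or
#' significance; reverse causation when the reverse IVW is significant or
#' Steiger filtering removed half or more of the instruments.
#'
#' @param stats named list with elements `q_pval`, `egger_intercept_p`,
#'   `presso_global_p`, `presso_n_outliers`, `presso_agree` (corrected
#'   estimate agrees with raw in sign and significance), `reverse_p`
#'   (`NA` when not evaluable), `steiger_retention` (fraction kept).
#' @param alpha flag level (default 0.05).
#' @return named logical vector: `heterogeneity`, `pleiotropy`, `outliers`,
#'   `reverse_causation`.
#' @export
sensitivity_flags <- function(stats, alpha = 0.05) {
  c(heterogeneity = isTRUE(stats$q_pval < alpha),
    pleiotropy = isTRUE(stats$egger_intercept_p < alpha) ||
      isTRUE(stats$presso_global_p < alpha),
    outliers = isTRUE(stats$presso_n_outliers > 0) &&
      !isTRUE(stats$presso_agree),
    reverse_causation = isTRUE(stats$reverse_p < alpha) ||
      isTRUE(stats$steiger_retention < 0.5))
}

#' Run the full sensitivity battery
#'
#' Aggregates Cochran's Q, the Egger intercept test, MR-PRESSO global and
#' outlier tests, leave-one-out, the Steiger retention summary, and reverse
#' MR into a single report with boolean flags (see [sensitivity_flags()]).
#'
#' @param iset an `instrument_set` from [build_instrument_set()].
#' @param exposure,outcome the original [summary_stats] (needed for reverse
#'   MR); pass `NULL` to skip reverse MR.
#' @param panel an [ld_panel] (reverse MR only).
#' @param config an [instrument_config()].
#' @param alpha flag level (default 0.05).
#' @param presso_n_sim,seed forwarded to [mr_presso()].
#' @return an object of class `sensitivity_report`.
#' @export
run_sensitivity_suite <- function(iset, exposure = NULL, outcome = NULL,
                                  panel = NULL,
                                  config = instrument_config(),
                                  alpha = 0.05, presso_n_sim = 1000,
                                  seed = NULL) {
  stopifnot(inherits(iset, "instrument_set"))
  rows <- iset$harmonized$rows
  n <- nrow(rows)
  q <- cochran_q(rows)
  egger <- tryCatch(mr_egger(rows), error = function(e) NULL)
  presso <- tryCatch(mr_presso(rows, n_sim = presso_n_sim, seed = seed),
                     error = function(e) NULL)
  loo <- tryCatch(leave_one_out(rows, alpha = alpha),
                  error = function(e) NULL)

  presso_agree <- NA
  if (!is.null(presso)) {
    raw <- presso$extras$raw
    presso_agree <- sign(presso$beta) == sign(raw$beta) &&
      (presso$pval < alpha) == (raw$pval < alpha)
  }
  steiger_kept <- if (!is.null(iset$steiger_report)) {
    sum(iset$steiger_report$kept)
  } else NA_integer_
  steiger_total <- if (!is.null(iset$steiger_report)) {
    nrow(iset$steiger_report)
  } else NA_integer_

  reverse <- if (!is.null(exposure) && !is.null(outcome) && !is.null(panel)) {
    reverse_mr(exposure, outcome, panel, config)
  } else {
    list(evaluable = FALSE, estimate = NULL, n_snp = 0L)
  }

  stats <- list(
    q_pval = q$pval,
    egger_intercept_p = if (!is.null(egger)) egger$extras$intercept_p else NA,
    presso_global_p = if (!is.null(presso)) presso$extras$global_p else NA,
    presso_n_outliers = if (!is.null(presso))
      length(presso$extras$outliers) else NA,
    presso_agree = presso_agree,
    reverse_p = if (reverse$evaluable) reverse$estimate$pval else NA,
    steiger_retention = if (!is.na(steiger_total) && steiger_total > 0)
      steiger_kept / steiger_total else NA
  )
  structure(
    list(q_stat = q$Q, q_df = q$df, q_pval = q$pval,
         egger_intercept = if (!is.null(egger)) egger$extras$intercept else NA,
         egger_intercept_p = stats$egger_intercept_p,
         presso_global_p = stats$presso_global_p,
         presso_outliers = if (!is.null(presso))
           presso$extras$outlier_snps else character(0),
         loo_estimates = if (!is.null(loo)) loo$estimates else NULL,
         loo_driver_flag = if (!is.null(loo)) loo$driver_flag else NA,
         steiger_summary = c(kept = steiger_kept,
                             dropped = steiger_total - steiger_kept),
         reverse_evaluable = reverse$evaluable,
         reverse_ivw = reverse$estimate,
         alpha = alpha,
         stats = stats,
         flags = sensitivity_flags(stats, alpha)),
    class = "sensitivity_report"
  )
}

#' @rdname run_sensitivity_suite
#' @param x a `sensitivity_report`.
#' @param ... unused.
#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report\n")
  cat(sprintf("  Cochran's Q = %.3g (df %d), p = %.3g\n",
              x$q_stat, x$q_df, x$q_pval))
  cat(sprintf("  Egger intercept = %.3g, p = %.3g\n",
              x$egger_intercept, x$egger_intercept_p))
  cat(sprintf("  MR-PRESSO global p = %.3g, outliers: %s\n",
              x$presso_global_p,
              if (length(x$presso_outliers)) paste(x$presso_outliers,
                                                   collapse = ", ") else
                "none"))
  cat(sprintf("  leave-one-out driver: %s\n", x$loo_driver_flag))
  cat(sprintf("  reverse MR: %s\n",
              if (x$reverse_evaluable)
                sprintf("p = %.3g", x$reverse_ivw$pval) else "not evaluable"))
  cat("  flags:", paste(names(x$flags)[x$flags], collapse = ", "),
      if (!any(x$flags)) "(none)", "\n")
  invisible(x)
}
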