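# Two-step (network) MR mediation calculus and the evidence-tier classifier.

#' Indirect (mediated) effect by the product of coefficients
#'
#' `indirect = beta1 * beta2` where `beta1` is the exposure-to-mediator
#' effect (univariable MR) and `beta2` the mediator-to-outcome effect
#' adjusted for the exposure (multivariable MR). The SE is first-order delta
#' method for independent two-sample estimates:
#' `sqrt(beta2^2*se1^2 + beta1^2*se2^2)`; the 95% CI is
#' `indirect +/- 1.96*SE`.
#'
#' @param beta1,se1 exposure-to-mediator estimate and SE.
#' @param beta2,se2 adjusted mediator-to-outcome estimate and SE.
#' @return list with `indirect`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
mediation_effect <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  indirect <- beta1 * beta2
  se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  ci <- ci_bounds(indirect, se)
  list(indirect = indirect, se = se, ci_low = ci[1], ci_high = ci[2],
       pval = if (se > 0) two_sided_p(indirect, se) else NA_real_)
}

#' Proportion of the total effect that is mediated
#'
#' `proportion = indirect / total`. The default CI is the delta method on
#' the ratio treating the two estimates as independent:
#' `Var = Var(IE)/TE^2 + IE^2*Var(TE)/TE^4` (a documented approximation —
#' the two-step estimates share the exposure instruments, and the covariance
#' is ignored). `method = "mc"` instead draws both estimates from their
#' normal approximations and reports the percentile interval.
#'
#' @param indirect,se_indirect the mediated effect and its SE.
#' @param total,se_total the total effect and its SE.
#' @param method `"delta"` (default) or `"mc"`.
#' @param n_draws Monte-Carlo draws when `method = "mc"` (default 10000).
#' @param seed optional RNG seed for the Monte-Carlo interval.
#' @return list with `proportion`, `se`, `ci_low`, `ci_high`.
#' @export
mediation_proportion <- function(indirect, se_indirect, total, se_total,
                                 method = c("delta", "mc"),
                                 n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  if (total == 0) stop("mediation proportion undefined: total effect is 0",
                       call. = FALSE)
  prop <- indirect / total
  if (method == "delta") {
    v <- se_indirect^2 / total^2 + indirect^2 * se_total^2 / total^4
    se <- sqrt(v)
    ci <- ci_bounds(prop, se)
  } else {
    draws <- with_seed(seed, {
      rnorm(n_draws, indirect, se_indirect) / rnorm(n_draws, total, se_total)
    })
    se <- stats::sd(draws)
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  list(proportion = prop, se = se, ci_low = ci[1], ci_high = ci[2])
}

#' Screen a candidate mediator
#'
#' A mediator is carried forward only when (1) the exposure influences the
#' mediator (univariable MR p < alpha), (2) the mediator affects the outcome
#' independently of the exposure (multivariable MR p < alpha after
#' adjustment), and (3) the sign of the mediated effect `beta1*beta2` agrees
#' with the sign of the total effect.
#'
#' @param uvmr_exp_to_med [mr_estimate][new_mr_estimate] of the exposure on
#'   the mediator (beta1).
#' @param mvmr_med_on_out [mr_estimate][new_mr_estimate] of the mediator on
#'   the outcome adjusted for the exposure (beta2).
#' @param total [mr_estimate][new_mr_estimate] of the exposure on the
#'   outcome.
#' @param alpha screening level (default 0.05).
#' @return list with `pass` and per-criterion booleans + machine-readable
#'   `reasons` for failures.
#' @export
screen_mediators <- function(uvmr_exp_to_med, mvmr_med_on_out, total,
                             alpha = 0.05) {
  c1 <- uvmr_exp_to_med$pval < alpha
  c2 <- mvmr_med_on_out$pval < alpha
  c3 <- sign(uvmr_exp_to_med$beta * mvmr_med_on_out$beta) == sign(total$beta)
  reasons <- c(
    if (!c1) "exposure does not influence mediator (criterion 1)",
    if (!c2) "mediator not independently associated with outcome (criterion 2)",
    if (!c3) "mediated effect direction inconsistent with total effect (criterion 3)"
  )
  list(pass = c1 && c2 && c3,
       criteria = c(influences_mediator = c1,
                    mediator_affects_outcome = c2,
                    sign_consistent = c3),
       reasons = reasons %||% character(0))
}

#' Classify the evidence tier of one exposure-outcome result
#'
#' "Probable causality" requires the primary (IVW) p-value below `alpha`,
#' at least three of the four secondary methods supporting it (secondary
#' p < alpha with the same effect sign as IVW), and all four sensitivity
#' flags off. "Causality" additionally requires the IVW p-value to pass the
#' Bonferroni threshold `alpha / n_exposures`.
#'
#' @param primary the IVW [mr_estimate][new_mr_estimate].
#' @param secondary list of up to four secondary estimates (ML, weighted
#'   median, MR-Egger, MR-PRESSO); a `NULL` entry counts as unsupportive
#'   with a warning.
#' @param flags named logical vector from [sensitivity_flags()]; `NULL`
#'   counts as all off.
#' @param n_exposures Bonferroni denominator: the number of exposures
#'   screened (default 196, the named gut-microbiota panel).
#' @param alpha nominal level (default 0.05).
#' @return an object of class `evidence_label`: list with `tier` (`"none"`,
#'   `"probable_causality"`, `"causality"`), `support_count`,
#'   `bonferroni_threshold`, and the consumed `flags`.
#' @export
classify_evidence <- function(primary, secondary, flags = NULL,
                              n_exposures = 196, alpha = 0.05) {
  stopifnot(inherits(primary, "mr_estimate"))
  missing_n <- sum(vapply(secondary, is.null, logical(1)))
  if (missing_n > 0) {
    warning(missing_n, " secondary estimate(s) missing; counted unsupportive",
            call. = FALSE)
  }
  support <- vapply(secondary, function(s) {
    !is.null(s) && s$pval < alpha && sign(s$beta) == sign(primary$beta)
  }, logical(1))
  support_count <- sum(support)
  flags_off <- is.null(flags) || !any(flags, na.rm = TRUE)
  bonf <- alpha / n_exposures
  probable <- primary$pval < alpha && support_count >= 3 && flags_off
  tier <- if (probable && primary$pval < bonf) "causality" else
    if (probable) "probable_causality" else "none"
  structure(
    list(tier = tier, support_count = support_count,
         support = support, bonferroni_threshold = bonf,
         flags = flags %||% c(heterogeneity = FALSE, pleiotropy = FALSE,
                              outliers = FALSE, reverse_causation = FALSE)),
    class = "evidence_label"
  )
}

#' @rdname classify_evidence
#' @param x an `evidence_label`.
#' @param ... unused.
#' @export
print.evidence_label <- function(x, ...) {
  cat(sprintf("evidence tier: %s (%d/%d secondary supportive, Bonferroni %g)\n",
              x$tier, x$support_count, length(x$support),
              x$bonferroni_threshold))
  invisible(x)
}

#' Run a full network (two-step) MR mediation analysis
#'
#' Orchestrates, for one exposure / mediator / outcome triplet:
#' the total effect (univariable MR exposure to outcome, with the full
#' estimator suite and sensitivity battery), beta1 (univariable MR exposure
#' to mediator), beta2 (multivariable MR mediator to outcome adjusted for
#' the exposure, with MVMR-Egger as robustness check), mediator screening,
#' the mediated effect and its proportion, and the evidence tier of the
#' total effect.
#'
#' @param exposure,mediator,outcome [summary_stats] objects.
#' @param panel an [ld_panel].
#' @param config an [instrument_config()].
#' @param n_exposures Bonferroni denominator for [classify_evidence()].
#' @param alpha nominal level (default 0.05).
#' @param seed optional seed for the stochastic estimator components.
#' @param presso_n_sim,wm_n_boot sizes of the MR-PRESSO simulation and the
#'   weighted-median bootstrap.
#' @param proportion_method `"delta"` (default) or `"mc"`, see
#'   [mediation_proportion()].
#' @return an object of class `mediation_result`; when any leg has no
#'   instruments, a structured not-evaluable result with the failing leg
#'   named.
#' @export
run_network_mr <- function(exposure, mediator, outcome, panel,
                           config = instrument_config(),
                           n_exposures = 196, alpha = 0.05, seed = NULL,
                           presso_n_sim = 1000, wm_n_boot = 1000,
                           proportion_method = "delta") {
  leg <- function(exp_ss, out_ss, what, cfg = config) {
    tryCatch(build_instrument_set(exp_ss, out_ss, panel, cfg),
             netmr_empty_selection = function(e) {
               structure(list(leg = what, message = conditionMessage(e)),
                         class = "netmr_leg_failure")
             })
  }
  not_evaluable <- function(fail) {
    structure(list(evaluable = FALSE, failed_leg = fail$leg,
                   message = fail$message),
              class = "mediation_result")
  }

  iset_total <- leg(exposure, outcome, "exposure->outcome")
  if (inherits(iset_total, "netmr_leg_failure")) {
    return(not_evaluable(iset_total))
  }
  ests <- mr_run(iset_total, seed = seed, presso_n_sim = presso_n_sim,
                 wm_n_boot = wm_n_boot)
  total <- ests$ivw
  sens <- run_sensitivity_suite(iset_total, exposure, outcome, panel,
                                config, alpha = alpha,
                                presso_n_sim = presso_n_sim, seed = seed)
  label <- classify_evidence(total, ests[c("ml", "wm", "egger", "presso")],
                             sens$flags, n_exposures = n_exposures,
                             alpha = alpha)

  # the outcome-association exclusion guards the exposure->outcome analyses
  # against reverse causation; on the exposure->mediator leg it would delete
  # instruments for being associated with the very trait whose effect beta1
  # estimates, so it is not applied there (Steiger still is)
  config_b1 <- config
  config_b1$outcome_p_max <- 0
  iset_b1 <- leg(exposure, mediator, "exposure->mediator", config_b1)
  if (inherits(iset_b1, "netmr_leg_failure")) return(not_evaluable(iset_b1))
  beta1 <- mr_ivw(iset_b1)

  mv <- tryCatch(
    build_mvmr_set(list(exposure, mediator), outcome, panel, config),
    error = function(e) {
      structure(list(leg = "mvmr", message = conditionMessage(e)),
                class = "netmr_leg_failure")
    })
  if (inherits(mv, "netmr_leg_failure")) return(not_evaluable(mv))
  mv_ivw <- mvmr_ivw(mv)
  mv_egger <- tryCatch(mvmr_egger(mv, orient_on = 1),
                       error = function(e) NULL)
  beta2 <- mv_ivw$estimates[[mediator$trait_id]]

  screen <- screen_mediators(beta1, beta2, total, alpha = alpha)
  indirect <- mediation_effect(beta1$beta, beta1$se, beta2$beta, beta2$se)
  proportion <- if (screen$pass && total$beta != 0) {
    mediation_proportion(indirect$indirect, indirect$se, total$beta,
                         total$se, method = proportion_method, seed = seed)
  } else NULL

  structure(
    list(evaluable = TRUE,
         exposure_id = exposure$trait_id, mediator_id = mediator$trait_id,
         outcome_id = outcome$trait_id,
         beta1 = beta1, beta2 = beta2, total = total,
         indirect = indirect, proportion = proportion,
         screen = screen, estimates = ests, sensitivity = sens,
         mvmr = list(ivw = mv_ivw, egger = mv_egger),
         label = label),
    class = "mediation_result"
  )
}

#' @rdname run_network_mr
#' @param x a `mediation_result`.
#' @param ... unused.
#' @export
print.mediation_result <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("mediation_result: not evaluable (%s: %s)\n",
                x$failed_leg, x$message))
    return(invisible(x))
  }
  cat(sprintf("mediation_result: %s -> %s -> %s\n",
              x$exposure_id, x$mediator_id, x$outcome_id))
  cat(sprintf("  total  = %.4g (p = %.3g), tier: %s\n",
              x$total$beta, x$total$pval, x$label$tier))
  cat(sprintf("  beta1  = %.4g (p = %.3g), beta2 = %.4g (p = %.3g)\n",
              x$beta1$beta, x$beta1$pval, x$beta2$beta, x$beta2$pval))
  cat(sprintf("  indirect = %.4g (95%% CI %.4g, %.4g)\n",
              x$indirect$indirect, x$indirect$ci_low, x$indirect$ci_high))
  if (!is.null(x$proportion)) {
    cat(sprintf("  proportion mediated = %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
                100 * x$proportion$proportion, 100 * x$proportion$ci_low,
                100 * x$proportion$ci_high))
  } else {
    cat(sprintf("  mediator screened out: %s\n",
                paste(x$screen$reasons, collapse = "; ")))
  }
  invisible(x)
}
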