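# Panel-scale orchestration: univariable screen across many exposures with
# sensitivity gating and evidence tiers, then network-MR mediation for
# tier-passing pairs.

#' Screen many exposures against one outcome
#'
#' For each exposure: full instrument cascade, the requested estimator
#' suite, the sensitivity battery, and the evidence tier. The Bonferroni
#' denominator is the number of exposures actually screened. Failures in one
#' pair are isolated: they are logged into that pair's row and never touch
#' other pairs.
#'
#' @param exposures named list of [summary_stats], or character paths read
#'   via [read_summary_stats()].
#' @param outcome a [summary_stats] or path.
#' @param panel an [ld_panel].
#' @param config an [instrument_config()].
#' @param methods estimator tags for [mr_run()].
#' @param alpha nominal level (default 0.05).
#' @param seed optional seed for stochastic estimator components.
#' @param presso_n_sim,wm_n_boot simulation sizes for MR-PRESSO / the
#'   weighted-median bootstrap.
#' @param reverse run reverse MR inside the sensitivity suite (default
#'   `TRUE`; the dominant cost at panel scale).
#' @return an object of class `screen_result`: `table` (one row per
#'   exposure-method, report-shaped: exposure, outcome, method, nSNP,
#'   p-value, beta, CI, judgment), `details` (per-exposure list with
#'   estimates, sensitivity report, label, provenance), and `log`
#'   (per-pair filter counts).
#' @export
run_uvmr_screen <- function(exposures, outcome, panel,
                            config = instrument_config(),
                            methods = c("ivw", "ml", "wm", "egger", "presso"),
                            alpha = 0.05, seed = NULL,
                            presso_n_sim = 1000, wm_n_boot = 1000,
                            reverse = TRUE) {
  as_ss <- function(x, id) {
    if (inherits(x, "summary_stats")) x else
      read_summary_stats(x, trait_id = id %||% basename(x))
  }
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(seq_along(exposures), function(i) {
      if (inherits(exposures[[i]], "summary_stats"))
        exposures[[i]]$trait_id else basename(as.character(exposures[[i]]))
    }, character(1))
  }
  exposures <- Map(as_ss, exposures, names(exposures))
  outcome <- as_ss(outcome, NULL)
  n_exposures <- length(exposures)

  details <- vector("list", n_exposures)
  names(details) <- names(exposures)
  log_lines <- list()
  rows <- list()

  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    nm <- names(exposures)[i]   # panel label, may differ from trait_id
    pair_seed <- if (is.null(seed)) NULL else seed + i
    res <- tryCatch({
      iset <- build_instrument_set(ex, outcome, panel, config)
      ests <- mr_run(iset, methods = methods, seed = pair_seed,
                     presso_n_sim = presso_n_sim, wm_n_boot = wm_n_boot)
      sens <- run_sensitivity_suite(
        iset,
        exposure = if (reverse) ex else NULL,
        outcome = if (reverse) outcome else NULL,
        panel = if (reverse) panel else NULL,
        config = config, alpha = alpha,
        presso_n_sim = presso_n_sim, seed = pair_seed)
      label <- classify_evidence(
        ests$ivw,
        ests[intersect(c("ml", "wm", "egger", "presso"), names(ests))],
        sens$flags, n_exposures = n_exposures, alpha = alpha)
      list(status = "ok", iset = iset, estimates = ests,
           sensitivity = sens, label = label)
    },
    netmr_empty_selection = function(e) {
      list(status = "no instruments", message = conditionMessage(e),
           provenance = e$provenance)
    },
    error = function(e) {
      list(status = "error", message = conditionMessage(e))
    })
    details[[i]] <- res

    if (res$status == "ok") {
      prov <- res$iset$provenance
      log_lines[[i]] <- data.frame(exposure = nm,
                                   outcome = outcome$trait_id,
                                   filter = prov$filter,
                                   removed = prov$removed,
                                   stringsAsFactors = FALSE)
      tab <- mr_table(res$estimates)
      tab <- cbind(exposure = nm, outcome = outcome$trait_id, tab,
                   judgment = ifelse(tab$method == "IVW",
                                     res$label$tier, ""),
                   stringsAsFactors = FALSE)
      rows[[i]] <- tab
    } else {
      rows[[i]] <- data.frame(exposure = nm,
                              outcome = outcome$trait_id,
                              method = NA_character_, n_snp = 0L,
                              beta = NA_real_, se = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              pval = NA_real_,
                              judgment = paste("not evaluable:", res$status),
                              stringsAsFactors = FALSE)
      prov <- res$provenance
      log_lines[[i]] <- data.frame(
        exposure = nm, outcome = outcome$trait_id,
        filter = if (!is.null(prov)) prov$filter else res$status,
        removed = if (!is.null(prov)) prov$removed else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         details = details,
         log = do.call(rbind, c(log_lines, list(make.row.names = FALSE))),
         n_exposures = n_exposures,
         bonferroni_threshold = alpha / n_exposures),
    class = "screen_result"
  )
}

#' @rdname run_uvmr_screen
#' @param x a `screen_result`.
#' @param ... unused.
#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d exposures (Bonferroni threshold %.3g)\n",
              x$n_exposures, x$bonferroni_threshold))
  tiers <- vapply(x$details, function(d) {
    if (d$status == "ok") d$label$tier else "not evaluable"
  }, character(1))
  print(table(tiers))
  invisible(x)
}

#' Run the full study: screen, then mediate
#'
#' Stage one screens every exposure against the outcome and assigns evidence
#' tiers; stage two runs network-MR mediation for every tier-passing
#' exposure crossed with every candidate mediator, emitting a mediation
#' table (beta1, beta2, indirect, total, proportion mediated with CIs).
#'
#' @inheritParams run_uvmr_screen
#' @param mediators named list of [summary_stats] (or paths).
#' @param min_tier exposures at this tier or better proceed to mediation
#'   (`"probable_causality"` default, or `"causality"`).
#' @return list of class `full_study_result`: `screen` (a `screen_result`),
#'   `mediation` (list of [run_network_mr()] results keyed
#'   `exposure|mediator`), and `mediation_table` (one row per evaluable
#'   pair).
#' @export
run_full_study <- function(exposures, mediators, outcome, panel,
                           config = instrument_config(),
                           methods = c("ivw", "ml", "wm", "egger", "presso"),
                           alpha = 0.05, seed = NULL,
                           presso_n_sim = 1000, wm_n_boot = 1000,
                           min_tier = "probable_causality") {
  screen <- run_uvmr_screen(exposures, outcome, panel, config,
                            methods = methods, alpha = alpha, seed = seed,
                            presso_n_sim = presso_n_sim,
                            wm_n_boot = wm_n_boot)
  ok_tiers <- if (min_tier == "causality") "causality" else
    c("probable_causality", "causality")
  passing <- names(Filter(function(d) {
    d$status == "ok" && d$label$tier %in% ok_tiers
  }, screen$details))

  as_ss <- function(x, id) {
    if (inherits(x, "summary_stats")) x else
      read_summary_stats(x, trait_id = id %||% basename(x))
  }
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(seq_along(mediators), function(i) {
      if (inherits(mediators[[i]], "summary_stats"))
        mediators[[i]]$trait_id else basename(as.character(mediators[[i]]))
    }, character(1))
  }
  mediators <- Map(as_ss, mediators, names(mediators))
  outcome_ss <- if (inherits(outcome, "summary_stats")) outcome else
    read_summary_stats(outcome, trait_id = basename(outcome))
  exposures_ss <- lapply(names(screen$details), function(nm) {
    # reuse the summary_stats objects materialized by the screen
    if (inherits(exposures[[nm]], "summary_stats")) exposures[[nm]] else
      read_summary_stats(exposures[[nm]], trait_id = nm)
  })
  names(exposures_ss) <- names(screen$details)

  mediation <- list()
  med_rows <- list()
  for (exp_id in passing) {
    for (med_id in names(mediators)) {
      key <- paste(exp_id, med_id, sep = "|")
      res <- tryCatch(
        run_network_mr(exposures_ss[[exp_id]], mediators[[med_id]],
                       outcome_ss, panel, config,
                       n_exposures = screen$n_exposures, alpha = alpha,
                       seed = seed, presso_n_sim = presso_n_sim,
                       wm_n_boot = wm_n_boot),
        error = function(e) {
          structure(list(evaluable = FALSE, failed_leg = "unexpected",
                         message = conditionMessage(e)),
                    class = "mediation_result")
        })
      mediation[[key]] <- res
      if (res$evaluable) {
        med_rows[[key]] <- data.frame(
          exposure = exp_id, mediator = med_id,
          outcome = outcome_ss$trait_id,
          beta1 = res$beta1$beta, beta1_p = res$beta1$pval,
          beta2 = res$beta2$beta, beta2_p = res$beta2$pval,
          total = res$total$beta, total_p = res$total$pval,
          indirect = res$indirect$indirect,
          indirect_low = res$indirect$ci_low,
          indirect_high = res$indirect$ci_high,
          screened_in = res$screen$pass,
          proportion = if (!is.null(res$proportion))
            res$proportion$proportion else NA_real_,
          proportion_low = if (!is.null(res$proportion))
            res$proportion$ci_low else NA_real_,
          proportion_high = if (!is.null(res$proportion))
            res$proportion$ci_high else NA_real_,
          stringsAsFactors = FALSE)
      } else {
        med_rows[[key]] <- data.frame(
          exposure = exp_id, mediator = med_id,
          outcome = outcome_ss$trait_id,
          beta1 = NA_real_, beta1_p = NA_real_, beta2 = NA_real_,
          beta2_p = NA_real_, total = NA_real_, total_p = NA_real_,
          indirect = NA_real_, indirect_low = NA_real_,
          indirect_high = NA_real_, screened_in = FALSE,
          proportion = NA_real_, proportion_low = NA_real_,
          proportion_high = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(screen = screen, mediation = mediation,
         mediation_table = if (length(med_rows))
           do.call(rbind, c(med_rows, list(make.row.names = FALSE))) else
             NULL),
    class = "full_study_result"
  )
}
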