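# Reproducible simulation studies used to validate the estimators and the
# mediation calculus against the generator's known truth. Each study is a
# plain function of a base seed so results are exactly reproducible.

#' Agreement of IVW and MVMR-IVW with a weighted-least-squares oracle
#'
#' Draws random instrument sets and compares the closed-form IVW (and
#' multivariable IVW) point estimates and fixed-effects SEs against
#' independently fitted weighted least-squares regressions ([stats::lm]).
#'
#' @param n_instances number of random instances (default 100).
#' @param seed base RNG seed.
#' @return list with `max_beta_dev`, `max_se_dev`, `max_mvmr_dev`: the
#'   largest absolute deviations observed.
#' @export
study_ivw_oracle <- function(n_instances = 100, seed = 1) {
  dev_b <- dev_s <- dev_m <- 0
  for (r in seq_len(n_instances)) {
    set.seed(seed + r)
    n <- sample(10:40, 1)
    g <- rnorm(n, 0, 0.1)
    rows <- data.frame(beta_exp = rnorm(n, g, 0.01), se_exp = 0.01,
                       beta_out = rnorm(n, 0.2 * g, 0.01),
                       se_out = runif(n, 0.005, 0.02))
    est <- mr_ivw(rows, effects_model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = rows,
              weights = 1 / rows$se_out^2)
    se_or <- sqrt(1 / sum(rows$beta_exp^2 / rows$se_out^2))
    dev_b <- max(dev_b, abs(est$beta - unname(coef(fit))))
    dev_s <- max(dev_s, abs(est$se - se_or))

    g2 <- rnorm(n, 0, 0.1)
    mrows <- data.frame(beta_e1 = rows$beta_exp, se_e1 = 0.01,
                        beta_e2 = rnorm(n, g2, 0.01), se_e2 = 0.01,
                        beta_out = rnorm(n, 0.2 * g + 0.3 * g2, 0.01),
                        se_out = rows$se_out)
    mv <- mvmr_ivw(mrows)
    mfit <- lm(beta_out ~ 0 + beta_e1 + beta_e2, data = mrows,
               weights = 1 / mrows$se_out^2)
    dev_m <- max(dev_m, max(abs(
      vapply(mv$estimates, `[[`, numeric(1), "beta") - coef(mfit))))
  }
  list(max_beta_dev = dev_b, max_se_dev = dev_s, max_mvmr_dev = dev_m)
}

#' Type-I error of the core estimators under the causal null
#'
#' Simulates triplets from [make_null_config()] (no causal effects, no
#' pleiotropy), harmonizes exposure and outcome, runs the chosen estimators,
#' and reports the fraction of replicates rejecting at `alpha`.
#'
#' @param reps replicates (default 1000).
#' @param n_snps instruments per replicate (default 30).
#' @param methods subset of `"ivw"`, `"ml"`, `"wm"`, `"egger"`.
#' @param alpha nominal level (default 0.05).
#' @param wm_n_boot weighted-median bootstrap size (default 1000).
#' @param seed base RNG seed.
#' @param config base [sim_config()] whose causal effects are nulled.
#' @return named numeric vector of rejection rates.
#' @export
study_type1_error <- function(reps = 1000, n_snps = 30,
                              methods = c("ivw", "ml", "wm", "egger"),
                              alpha = 0.05, wm_n_boot = 1000, seed = 1,
                              config = sim_config(n_snps = n_snps,
                                                  n_snps_med = 0,
                                                  n_snps_out = 0)) {
  config <- make_null_config(config)
  rej <- matrix(FALSE, reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    config$seed <- seed + r
    sim <- simulate_gwas_triplet(config)
    rows <- harmonize(sim$exposure, sim$outcome)$rows
    for (m in methods) {
      p <- switch(m,
                  ivw = mr_ivw(rows)$pval,
                  ml = mr_ml(rows)$pval,
                  wm = mr_weighted_median(rows, n_boot = wm_n_boot,
                                          seed = seed + r)$pval,
                  egger = mr_egger(rows)$pval)
      rej[r, m] <- p < alpha
    }
  }
  colMeans(rej)
}

#' Confidence-interval coverage under a true causal effect
#'
#' Simulates strong-instrument triplets with a purely direct exposure-
#' outcome effect `beta_total`, harmonizes, and reports each estimator's
#' 95% CI coverage of the truth.
#'
#' @param reps replicates (default 500).
#' @param n_snps instruments (default 100).
#' @param beta_total true causal effect (default 0.1).
#' @param mean_f target mean instrument F (default 100, the
#'   strong-instrument regime).
#' @param methods subset of `"ivw"`, `"ml"`, `"divw"`, `"raps"`.
#' @param seed base RNG seed.
#' @return named numeric vector of coverage rates.
#' @export
study_ci_coverage <- function(reps = 500, n_snps = 100, beta_total = 0.1,
                              mean_f = 100,
                              methods = c("ivw", "ml", "divw", "raps"),
                              seed = 1) {
  cov <- matrix(FALSE, reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    sim <- simulate_gwas_triplet(sim_config(
      n_snps = n_snps, n_snps_med = 0, n_snps_out = 0, mean_f = mean_f,
      beta_EM = 0, beta_MO = 0, beta_EO_direct = beta_total,
      seed = seed + r))
    rows <- harmonize(sim$exposure, sim$outcome)$rows
    for (m in methods) {
      est <- switch(m,
                    ivw = mr_ivw(rows),
                    ml = mr_ml(rows),
                    divw = mr_divw(rows),
                    raps = mr_raps(rows))
      cov[r, m] <- est$ci_low <= beta_total && beta_total <= est$ci_high
    }
  }
  colMeans(cov)
}

#' MR-PRESSO detection of a planted gross outlier
#'
#' Plants a `shift_sd`-standard-error shift on one instrument's outcome
#' effect and reports how often MR-PRESSO's Bonferroni outlier test flags
#' exactly that SNP, plus how often the outlier-corrected estimate falls
#' within 2 SE of the generative truth.
#'
#' @param n_seeds number of independent simulated datasets (default 100).
#' @param n_snps instruments (default 25).
#' @param shift_sd planted shift in SE units (default 10).
#' @param beta_total true causal effect (default 0.1).
#' @param n_sim MR-PRESSO simulation size (default 1000).
#' @param seed base RNG seed.
#' @return list with `detection_rate`, `within_2se_rate`, and
#'   `mean_abs_z` (mean |corrected - truth| / SE).
#' @export
study_presso_detection <- function(n_seeds = 100, n_snps = 25,
                                   shift_sd = 10, beta_total = 0.1,
                                   n_sim = 1000, seed = 1) {
  hit <- within2 <- logical(n_seeds)
  zdev <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    sim <- simulate_gwas_triplet(sim_config(
      n_snps = n_snps, n_snps_med = 0, n_snps_out = 0, mean_f = 60,
      beta_EM = 0, beta_MO = 0, beta_EO_direct = beta_total,
      seed = seed + r))
    spiked <- spike_outliers(sim$outcome, 4, shift_sd = shift_sd)
    rows <- harmonize(sim$exposure, spiked)$rows
    pr <- mr_presso(rows, n_sim = n_sim, seed = seed + r)
    hit[r] <- sim$outcome$records$snp_id[4] %in% pr$extras$outlier_snps
    zdev[r] <- abs(pr$beta - beta_total) / pr$se
    within2[r] <- zdev[r] <= 2
  }
  list(detection_rate = mean(hit), within_2se_rate = mean(within2),
       mean_abs_z = mean(zdev))
}

#' Recovery of the mediation proportion over replicated two-step analyses
#'
#' Runs the full two-step machinery (instrument cascade on each leg,
#' multivariable MR for the conditional mediator effect, delta-method
#' proportion CI) on replicated triplets drawn from `config` and reports
#' the CI's coverage of the generative mediation proportion, plus the
#' agreement between the delta-method SE of the indirect effect and a
#' large parametric Monte-Carlo SE.
#'
#' @param reps replicates (default 500).
#' @param config generator settings; defaults to the canonical mediated
#'   graph (`beta_EM = 0.5`, `beta_MO = 0.1`, direct 0.15, proportion 25%)
#'   with strong instruments (`mean_f = 100`) so that instrument selection
#'   is non-truncating and the two-step calculus itself is what is tested.
#' @param mc_draws Monte-Carlo draws for the delta-SE check (default 10000).
#' @param seed base RNG seed.
#' @return list with `coverage`, `mean_proportion`, `true_proportion`,
#'   `delta_se`, `mc_se`, `se_rel_dev`.
#' @export
study_mediation_recovery <- function(reps = 500,
                                     config = sim_config(mean_f = 100),
                                     mc_draws = 10000, seed = 1) {
  icfg <- instrument_config()
  icfg_b1 <- instrument_config(outcome_p_max = 0)
  cover <- logical(reps)
  props <- b1s <- b2s <- se1s <- se2s <- numeric(reps)
  truep <- simulate_gwas_triplet(config)$truth$true_proportion
  for (r in seq_len(reps)) {
    config$seed <- seed + r
    sim <- simulate_gwas_triplet(config)
    total <- mr_ivw(build_instrument_set(sim$exposure, sim$outcome,
                                         sim$panel, icfg))
    b1 <- mr_ivw(build_instrument_set(sim$exposure, sim$mediator,
                                      sim$panel, icfg_b1))
    mv <- build_mvmr_set(list(sim$exposure, sim$mediator), sim$outcome,
                         sim$panel, icfg)
    b2 <- mvmr_ivw(mv)$estimates[[2]]
    ie <- mediation_effect(b1$beta, b1$se, b2$beta, b2$se)
    pr <- mediation_proportion(ie$indirect, ie$se, total$beta, total$se)
    cover[r] <- pr$ci_low <= truep && truep <= pr$ci_high
    props[r] <- pr$proportion
    b1s[r] <- b1$beta; se1s[r] <- b1$se
    b2s[r] <- b2$beta; se2s[r] <- b2$se
  }
  # delta SE vs Monte-Carlo SE of the product, at the mean leg estimates
  delta_se <- mediation_effect(mean(b1s), mean(se1s), mean(b2s),
                               mean(se2s))$se
  set.seed(seed)
  mc <- rnorm(mc_draws, mean(b1s), mean(se1s)) *
    rnorm(mc_draws, mean(b2s), mean(se2s))
  mc_se <- stats::sd(mc)
  list(coverage = mean(cover), mean_proportion = mean(props),
       true_proportion = truep, delta_se = delta_se, mc_se = mc_se,
       se_rel_dev = abs(delta_se - mc_se) / mc_se)
}
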