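# Synthetic two-sample GWAS summary statistics under a known
# exposure -> mediator -> outcome linear causal graph, so every pipeline
# stage can be exercised offline against known truth.

#' Simulation configuration
#'
#' Defines the generative model. Three non-overlapping GWAS samples (the
#' two-sample design) measure an exposure, a mediator and an outcome linked
#' by a linear causal graph: `n_snps` instruments act on the exposure with
#' effects `gamma ~ N(0, sd)` calibrated so the expected mean per-SNP F
#' statistic equals `mean_f`; `n_snps_med` SNPs act directly on the mediator
#' and `n_snps_out` directly on the outcome (these give the mediator its own
#' instruments — without them the multivariable design would be collinear by
#' construction — and give reverse MR something to select). Implied true
#' associations: the mediator effect of an exposure SNP is
#' `gamma * beta_EM`, and its outcome effect is
#' `gamma * (beta_EO_direct + beta_EM * beta_MO) + alpha`, where `alpha` is
#' a pleiotropic effect drawn for a fraction `fraction_invalid` of exposure
#' SNPs from `N(mean_alpha, sd_alpha)` (plus `0.3 * gamma` when
#' `inside_violation`, correlating instrument strength with the direct
#' effect). A nonzero `reverse_effect` leaks the outcome-specific SNPs'
#' effects into the exposure. Sampling noise per trait is
#' `N(0, 1/(2*maf*(1-maf)*n))`, the standardized-trait approximation, with
#' allele frequencies uniform on `maf_range`. Exposure instruments fall into
#' LD blocks of `ld_block_size` SNPs with pairwise panel r² `ld_within_r2`
#' (true effects within a block share an exchangeable correlation
#' `sqrt(ld_within_r2)`).
#'
#' Default sample sizes: a microbial-abundance exposure GWAS of 14,306 (the
#' largest published 16S microbial-QTL meta-analysis), a mediator GWAS of
#' 7,700 (the scale of published gut metabolic-pathway abundance GWAS), and
#' an outcome GWAS of 20,000 — for binary traits read as the effective
#' sample size `4/(1/n_cases + 1/n_controls)`, a representative value for
#' clinically ascertained sleep phenotypes. These sizes keep valid
#' instruments' implied downstream associations below the
#' outcome-association exclusion threshold on average, the regime in which
#' the selection cascade operates on real data; with much larger downstream
#' samples and the default effect sizes the exclusion filter would remove
#' most valid instruments by design. The default causal effects
#' (`beta_EM = 0.5`, `beta_MO = 0.1`, `beta_EO_direct = 0.15`) give a total
#' effect of 0.2 and a true mediation proportion of 25%.
#'
#' @param n_snps exposure instruments (default 100).
#' @param n_snps_med mediator-specific instruments (default 50).
#' @param n_snps_out outcome-specific instruments (default 50).
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param maf_range uniform bounds for allele frequencies.
#' @param mean_f target mean per-SNP F statistic in each trait's own
#'   instruments (default 30).
#' @param beta_EM exposure-to-mediator effect.
#' @param beta_MO mediator-to-outcome conditional effect.
#' @param beta_EO_direct direct exposure-to-outcome effect.
#' @param fraction_invalid fraction of exposure SNPs with pleiotropic
#'   outcome effects.
#' @param mean_alpha,sd_alpha pleiotropic-effect distribution (directional
#'   when `mean_alpha != 0`, balanced when 0).
#' @param inside_violation correlate pleiotropy with instrument strength.
#' @param reverse_effect outcome-to-exposure coefficient (default 0).
#' @param ld_block_size,ld_within_r2 LD block structure of the exposure
#'   instruments (defaults 1 and 0: independent SNPs).
#' @param palindrome_frac fraction of SNPs assigned A/T or C/G allele pairs
#'   (default 0).
#' @param seed RNG seed (default 1).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100, n_snps_med = 50, n_snps_out = 50,
                       n_exp = 14306, n_med = 7700, n_out = 20000,
                       maf_range = c(0.05, 0.5), mean_f = 30,
                       beta_EM = 0.5, beta_MO = 0.1, beta_EO_direct = 0.15,
                       fraction_invalid = 0, mean_alpha = 0, sd_alpha = 0,
                       inside_violation = FALSE, reverse_effect = 0,
                       ld_block_size = 1, ld_within_r2 = 0,
                       palindrome_frac = 0, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_snps >= 1, cfg$n_exp >= 100, cfg$n_med >= 100,
            cfg$n_out >= 100,
            cfg$fraction_invalid >= 0, cfg$fraction_invalid <= 1,
            cfg$palindrome_frac >= 0, cfg$palindrome_frac <= 1,
            cfg$ld_within_r2 >= 0, cfg$ld_within_r2 < 1,
            cfg$ld_block_size >= 1, cfg$mean_f > 1,
            length(cfg$maf_range) == 2, cfg$maf_range[1] > 0,
            cfg$maf_range[2] < 1, cfg$maf_range[1] < cfg$maf_range[2])
  class(cfg) <- "sim_config"
  cfg
}

#' Null configuration for calibration studies
#'
#' Returns the base configuration with every causal effect zeroed
#' (exposure-to-mediator, mediator-to-outcome, direct, reverse); the
#' pleiotropy settings are left untouched. Used for type-I-error suites.
#'
#' @param base a [sim_config()].
#' @return a `sim_config` under the global causal null.
#' @export
make_null_config <- function(base = sim_config()) {
  base$beta_EM <- 0
  base$beta_MO <- 0
  base$beta_EO_direct <- 0
  base$reverse_effect <- 0
  base
}

# Allele pairs: non-palindromic by default, palindromic for a chosen subset.
draw_alleles <- function(n, palindrome_frac) {
  nonpal <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- runif(n) < palindrome_frac
  pick_np <- nonpal[sample.int(nrow(nonpal), n, replace = TRUE), , drop = FALSE]
  pick_p <- pal[sample.int(nrow(pal), n, replace = TRUE), , drop = FALSE]
  out <- pick_np
  out[is_pal, ] <- pick_p[is_pal, ]
  out
}

#' Simulate a two-sample GWAS triplet with known truth
#'
#' Draws allele frequencies, true per-SNP effects and pleiotropy per the
#' configuration, adds independent sampling noise for each of the three
#' GWAS samples, and returns validated [summary_stats] for exposure,
#' mediator and outcome, a matching [ld_panel], and the ground truth.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `exposure`, `mediator`, `outcome` ([summary_stats]),
#'   `panel` ([ld_panel]), and `truth` (class `sim_truth`: per-SNP true
#'   effects, pleiotropic effects `alpha`, invalid-SNP ids, `beta_total
#'   = beta_EO_direct + beta_EM*beta_MO`, and `true_proportion =
#'   beta_EM*beta_MO/beta_total`, `NA` under a null total effect).
#' @export
simulate_gwas_triplet <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_e <- cfg$n_snps; n_m <- cfg$n_snps_med; n_o <- cfg$n_snps_out
    n_all <- n_e + n_m + n_o
    role <- rep(c("exp", "med", "out"), c(n_e, n_m, n_o))
    snp_id <- sprintf("rs%05d", seq_len(n_all))
    maf <- runif(n_all, cfg$maf_range[1], cfg$maf_range[2])
    alleles <- draw_alleles(n_all, cfg$palindrome_frac)

    # per-trait sampling SDs under the standardized-trait approximation
    sd_trait <- function(n) sqrt(1 / (2 * maf * (1 - maf) * n))
    sd_e <- sd_trait(cfg$n_exp)
    sd_m <- sd_trait(cfg$n_med)
    sd_o <- sd_trait(cfg$n_out)

    # instrument effects calibrated to the target mean F: for a trait's own
    # instruments, E[mean F] = sd_effect^2 * mean(1/sd^2) + 1
    calib <- function(idx, sds) {
      sqrt((cfg$mean_f - 1) / mean(1 / sds[idx]^2))
    }
    gamma <- numeric(n_all)   # true effect on exposure
    delta <- numeric(n_all)   # direct effect on mediator
    eta <- numeric(n_all)     # direct effect on outcome
    ie <- which(role == "exp"); im <- which(role == "med")
    io <- which(role == "out")
    # exposure instruments, with exchangeable within-block correlation
    sd_g <- calib(ie, sd_e)
    if (cfg$ld_block_size > 1 && cfg$ld_within_r2 > 0) {
      rho <- sqrt(cfg$ld_within_r2)
      blk <- ceiling(seq_along(ie) / cfg$ld_block_size)
      z0 <- rnorm(max(blk))[blk]
      gamma[ie] <- sd_g * (sqrt(rho) * z0 +
                             sqrt(1 - rho) * rnorm(length(ie)))
    } else {
      gamma[ie] <- rnorm(length(ie), 0, sd_g)
    }
    if (n_m > 0) delta[im] <- rnorm(n_m, 0, calib(im, sd_m))
    if (n_o > 0) eta[io] <- rnorm(n_o, 0, calib(io, sd_o))

    # pleiotropy on exposure instruments
    alpha <- numeric(n_all)
    invalid <- integer(0)
    if (cfg$fraction_invalid > 0 && length(ie) > 0) {
      n_inv <- round(cfg$fraction_invalid * length(ie))
      invalid <- sample(ie, n_inv)
      alpha[invalid] <- rnorm(n_inv, cfg$mean_alpha, cfg$sd_alpha)
      if (cfg$inside_violation) {
        alpha[invalid] <- alpha[invalid] + 0.3 * gamma[invalid]
      }
    }

    beta_total <- cfg$beta_EO_direct + cfg$beta_EM * cfg$beta_MO
    true_exp <- gamma + cfg$reverse_effect * eta
    true_med <- gamma * cfg$beta_EM + delta
    true_out <- gamma * beta_total + alpha + delta * cfg$beta_MO + eta

    # positions: one block per megabase, chromosomes round-robin; SNPs of a
    # block sit 10 kb apart so the clumping window sees them
    blk_all <- ceiling(seq_len(n_all) / max(1, cfg$ld_block_size))
    chrom <- as.character((blk_all - 1) %% 22 + 1)
    pos <- 1e6 * ceiling(blk_all / 22) +
      1e4 * (seq_len(n_all) - (blk_all - 1) * max(1, cfg$ld_block_size))

    make_ss <- function(truth, sds, n, trait_id) {
      beta_hat <- rnorm(n_all, truth, sds)
      summary_stats(
        data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = alleles[, 1], other_allele = alleles[, 2],
                   eaf = maf, beta = beta_hat, se = sds,
                   pval = two_sided_p(beta_hat, sds), n = n,
                   stringsAsFactors = FALSE),
        trait_id = trait_id, sample_size = n)
    }
    exposure <- make_ss(true_exp, sd_e, cfg$n_exp, "exposure")
    mediator <- make_ss(true_med, sd_m, cfg$n_med, "mediator")
    outcome <- make_ss(true_out, sd_o, cfg$n_out, "outcome")

    # block-diagonal r2 panel matching the block structure
    r2 <- diag(n_all)
    if (cfg$ld_block_size > 1 && cfg$ld_within_r2 > 0) {
      same_block <- outer(blk_all, blk_all, "==")
      r2[same_block] <- cfg$ld_within_r2
      diag(r2) <- 1
    }
    panel <- ld_panel(snp_id, r2,
                      data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                                 stringsAsFactors = FALSE))

    truth <- structure(
      list(config = cfg, snp_id = snp_id, role = role,
           gamma = gamma, delta = delta, eta = eta, alpha = alpha,
           invalid_snps = snp_id[invalid],
           beta_total = beta_total,
           true_proportion = if (beta_total != 0)
             cfg$beta_EM * cfg$beta_MO / beta_total else NA_real_),
      class = "sim_truth")

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         panel = panel, truth = truth)
  })
}

#' Plant outlier SNPs in a summary-statistics table
#'
#' Shifts the chosen SNPs' effects by `shift_sd` standard errors (and
#' recomputes their p-values), emulating gross horizontal pleiotropy for
#' outlier-detection studies.
#'
#' @param stats a [summary_stats] object.
#' @param indices integer positions (or SNP ids) of records to shift.
#' @param shift_sd shift in units of each record's SE.
#' @param seed unused for the deterministic shift; kept for interface
#'   stability.
#' @return the modified [summary_stats]; attribute `planted_outliers` holds
#'   the affected SNP ids.
#' @export
spike_outliers <- function(stats, indices, shift_sd, seed = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  if (is.character(indices)) {
    indices <- match(indices, stats$records$snp_id)
  }
  if (anyNA(indices) || any(indices < 1) ||
      any(indices > nrow(stats$records))) {
    stop("outlier indices out of range", call. = FALSE)
  }
  r <- stats$records
  r$beta[indices] <- r$beta[indices] + shift_sd * r$se[indices]
  r$pval[indices] <- two_sided_p(r$beta[indices], r$se[indices])
  stats$records <- r
  attr(stats, "planted_outliers") <- r$snp_id[indices]
  stats
}

#' Write a simulated triplet to a directory as delimited text
#'
#' @param sim a [simulate_gwas_triplet()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_triplet <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_panel(sim$panel, file.path(dir, "ld_matrix.tsv"),
                 file.path(dir, "ld_positions.tsv"))
  truth <- sim$truth
  write.table(
    data.frame(snp_id = truth$snp_id, role = truth$role, gamma = truth$gamma,
               delta = truth$delta, eta = truth$eta, alpha = truth$alpha,
               stringsAsFactors = FALSE),
    file.path(dir, "truth_snps.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(c(
    sprintf("beta_total\t%.10g", truth$beta_total),
    sprintf("true_proportion\t%.10g", truth$true_proportion)),
    file.path(dir, "truth_effects.tsv"))
  invisible(dir)
}
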