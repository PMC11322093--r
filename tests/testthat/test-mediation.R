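# Mediation calculus, mediator screening, and the evidence-tier classifier.

test_that("the product-of-coefficients effect and delta SE are exact", {
  m <- mediation_effect(0.2, 0.05, 0.5, 0.1)
  expect_equal(m$indirect, 0.1)
  expect_equal(m$se, 0.03201562, tolerance = 1e-7)
  expect_equal(m$ci_low, 0.1 - qnorm(0.975) * m$se)

  # null beta1: SE collapses to |beta2| * se1
  m0 <- mediation_effect(0, 0.05, 0.5, 0.1)
  expect_equal(m0$indirect, 0)
  expect_equal(m0$se, 0.5 * 0.05)
})

test_that("the delta SE matches a large Monte-Carlo oracle within 10%", {
  set.seed(8)
  draws <- rnorm(10000, 0.2, 0.05) * rnorm(10000, 0.5, 0.1)
  m <- mediation_effect(0.2, 0.05, 0.5, 0.1)
  expect_lt(abs(m$se - sd(draws)) / sd(draws), 0.1)
})

test_that("the mediation proportion and its delta CI behave as a ratio", {
  p <- mediation_proportion(0.004, 0.001, 0.032, 0.008)
  expect_equal(p$proportion, 0.125)
  # delta variance of the ratio
  v <- 0.001^2 / 0.032^2 + 0.004^2 * 0.008^2 / 0.032^4
  expect_equal(p$se, sqrt(v), tolerance = 1e-12)
  expect_equal(mediation_proportion(0.032, 0.001, 0.032, 0.001)$proportion, 1)
  expect_error(mediation_proportion(0.1, 0.01, 0, 0.01), "undefined")

  # scale-free: rescaling the mediator's units leaves the proportion alone
  p2 <- mediation_proportion(0.004, 0.001, 0.032, 0.008)
  p3 <- mediation_proportion(0.2 * 5 * 0.02 / 5, 0.001, 0.032, 0.008)
  expect_equal(p2$proportion, p3$proportion)

  # Monte-Carlo interval agrees roughly when the total is well determined
  pmc <- mediation_proportion(0.004, 0.001, 0.032, 0.002, method = "mc",
                              seed = 1)
  expect_lt(abs(pmc$proportion - 0.125), 1e-12)
  expect_lt(abs(pmc$se - mediation_proportion(0.004, 0.001, 0.032,
                                              0.002)$se), 0.01)
})

test_that("mediator screening applies the three criteria", {
  est <- function(beta, p) new_mr_estimate("IVW", beta, abs(beta) / 2,
                                           10, pval = p)
  pass <- screen_mediators(est(0.5, 0.01), est(0.1, 0.02), est(0.2, 0.001))
  expect_true(pass$pass)
  f2 <- screen_mediators(est(0.5, 0.01), est(0.1, 0.3), est(0.2, 0.001))
  expect_false(f2$pass)
  expect_match(f2$reasons, "criterion 2")
  f3 <- screen_mediators(est(0.5, 0.01), est(0.1, 0.02), est(-0.2, 0.001))
  expect_false(f3$pass)
  expect_match(f3$reasons, "criterion 3")
})

test_that("evidence tiers reproduce the published classification rules", {
  est <- function(beta, p, m = "x") new_mr_estimate(m, beta, abs(beta) / 4,
                                                    12, pval = p)
  flags_off <- c(heterogeneity = FALSE, pleiotropy = FALSE,
                 outliers = FALSE, reverse_causation = FALSE)
  # the strongest insomnia association: IVW p 1.08e-4 < 0.05/196, all four
  # secondary methods significant and same-signed
  sec <- list(ml = est(0.033, 1.60e-4), wm = est(0.045, 1.00e-4),
              egger = est(0.041, 1.47e-1), presso = est(0.032, 8.80e-4))
  lab <- classify_evidence(est(0.032, 1.08e-4), sec, flags_off)
  expect_equal(lab$tier, "causality")
  expect_equal(lab$support_count, 3)  # Egger not significant
  expect_equal(lab$bonferroni_threshold, 0.05 / 196)

  # probable causality: IVW p 1.50e-2 above the Bonferroni bound
  sec2 <- list(ml = est(0.018, 5.99e-3), wm = est(0.027, 2.30e-3),
               egger = est(0.017, 3.18e-1), presso = est(0.017, 2.71e-2))
  lab2 <- classify_evidence(est(0.017, 1.50e-2), sec2, flags_off)
  expect_equal(lab2$tier, "probable_causality")

  # fewer than three supportive secondary methods: no tier
  sec3 <- list(ml = est(0.02, 0.01), wm = est(0.02, 0.2),
               egger = est(0.02, 0.3), presso = est(0.02, 0.04))
  lab3 <- classify_evidence(est(0.02, 0.04), sec3, flags_off)
  expect_equal(lab3$tier, "none")

  # any raised flag blocks both tiers
  flag_on <- replace(flags_off, "pleiotropy", TRUE)
  expect_equal(classify_evidence(est(0.032, 1.08e-4), sec, flag_on)$tier,
               "none")
  # opposite-signed secondary estimates do not count as support
  sec4 <- list(ml = est(-0.03, 1e-4), wm = est(0.03, 1e-4),
               egger = est(0.03, 1e-4), presso = est(0.03, 1e-4))
  expect_equal(classify_evidence(est(0.03, 1e-3), sec4,
                                 flags_off)$support_count, 3)
  # a missing secondary estimate counts as unsupportive, with a warning
  expect_warning(
    lab5 <- classify_evidence(est(0.03, 1e-3),
                              list(ml = est(0.03, 1e-4), wm = NULL,
                                   egger = NULL, presso = NULL), flags_off),
    "missing")
  expect_equal(lab5$support_count, 1)
})

test_that("classification is monotone in the secondary p-values", {
  est <- function(beta, p, m = "x") new_mr_estimate(m, beta, abs(beta) / 4,
                                                    12, pval = p)
  flags_off <- c(heterogeneity = FALSE, pleiotropy = FALSE,
                 outliers = FALSE, reverse_causation = FALSE)
  rank <- c(none = 0, probable_causality = 1, causality = 2)
  set.seed(9)
  for (i in 1:20) {
    ps <- runif(4)
    sec <- lapply(ps, function(p) est(0.03, p))
    base <- classify_evidence(est(0.03, 1e-4), sec, flags_off)
    j <- sample(4, 1)
    sec_better <- sec
    sec_better[[j]] <- est(0.03, ps[j] / 10)
    better <- classify_evidence(est(0.03, 1e-4), sec_better, flags_off)
    expect_gte(rank[[better$tier]], rank[[base$tier]])
  }
})

test_that("a full synthetic triplet is recovered end to end", {
  sim <- simulate_gwas_triplet(sim_config(seed = 101))
  res <- run_network_mr(sim$exposure, sim$mediator, sim$outcome, sim$panel,
                        seed = 5, presso_n_sim = 300, wm_n_boot = 300)
  expect_true(res$evaluable)
  expect_true(res$screen$pass)
  # every leg within 2 SE of its generative value
  expect_lt(abs(res$total$beta - 0.2), 2 * res$total$se)
  expect_lt(abs(res$beta1$beta - 0.5), 2 * res$beta1$se)
  expect_lt(abs(res$beta2$beta - 0.1), 2 * res$beta2$se)
  expect_lt(abs(res$indirect$indirect - 0.05), 2 * res$indirect$se)
  expect_true(res$proportion$ci_low <= 0.25 &&
                0.25 <= res$proportion$ci_high)

  # determinism: identical seeds give identical results
  res2 <- run_network_mr(sim$exposure, sim$mediator, sim$outcome, sim$panel,
                         seed = 5, presso_n_sim = 300, wm_n_boot = 300)
  expect_equal(res2$proportion, res$proportion)
  expect_equal(res2$total$beta, res$total$beta)

  # a mediator with no conditional effect is screened out
  simd <- simulate_gwas_triplet(sim_config(beta_MO = 0,
                                           beta_EO_direct = 0.2,
                                           seed = 102))
  resd <- run_network_mr(simd$exposure, simd$mediator, simd$outcome,
                         simd$panel, seed = 5, presso_n_sim = 300,
                         wm_n_boot = 300)
  expect_true(resd$evaluable)
  expect_false(resd$screen$pass)
  expect_null(resd$proportion)
})
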