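# Core estimators: Wald ratios, IVW, ML, weighted median, Egger.

test_that("Wald ratios follow the first-order formulas", {
  wr <- wald_ratios(make_rows(bx = c(0.1, 0.2), by = c(0.05, 0),
                              sx = 0.02, sy = 0.01))
  expect_equal(wr$ratio, c(0.5, 0))
  expect_equal(wr$se, c(0.1, 0.05))
  expect_error(wald_ratios(make_rows(bx = 0, by = 0.1, sx = 0.02,
                                     sy = 0.01)), "undefined")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  for (seed in 1:20) {
    rows <- random_rows(20, beta = 0.2, seed = seed)
    est <- mr_ivw(rows, effects_model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = rows,
              weights = 1 / rows$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    # fixed-effects SE: (sum w)^(-1/2) with w = bx^2/sy^2
    expect_equal(est$se,
                 1 / sqrt(sum(rows$beta_exp^2 / rows$se_out^2)),
                 tolerance = 1e-12)
    # Q equals the residual weighted RSS of the fit
    expect_equal(est$extras$Q,
                 sum(residuals(fit)^2 / rows$se_out^2), tolerance = 1e-8)
  }
})

test_that("IVW handles exact-ratio data and enforces preconditions", {
  rows <- make_rows(bx = c(0.1, 0.2), by = c(0.02, 0.04), sx = 0.02,
                    sy = 0.01)
  est <- mr_ivw(rows)
  expect_equal(est$beta, 0.2)
  expect_equal(est$extras$Q, 0)
  expect_equal(est$extras$effects_model, "fixed")
  expect_error(mr_ivw(rows[1, ]), "at least 2")
})

test_that("random-effects inflation engages only under overdispersion", {
  rows <- random_rows(30, beta = 0.1, seed = 4)
  rows$beta_out <- rows$beta_out + rnorm(30, 0, 0.05)  # heterogeneity
  fixed <- mr_ivw(rows, "fixed")
  auto <- mr_ivw(rows, "auto")
  expect_equal(auto$extras$effects_model, "random")
  expect_equal(auto$se,
               fixed$se * sqrt(auto$extras$Q / (auto$n_snp - 1)))
  expect_gt(auto$se, fixed$se)
})

test_that("ML approaches IVW as exposure SEs vanish and fits exact ratios", {
  rows <- random_rows(25, beta = 0.15, seed = 7)
  rows$se_exp <- 1e-8
  expect_equal(mr_ml(rows)$beta, mr_ivw(rows, "fixed")$beta,
               tolerance = 1e-6)
  exact <- make_rows(bx = c(0.1, 0.2), by = c(0.02, 0.04), sx = 0.02,
                     sy = 0.01)
  expect_equal(mr_ml(exact)$beta, 0.2, tolerance = 1e-8)
})

test_that("ML confidence intervals cover a true effect at nominal rate", {
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    rows <- sim_instrument_rows(sim_config(n_snps = 50, n_snps_med = 0,
                                           n_snps_out = 0, mean_f = 100,
                                           beta_EM = 0, beta_MO = 0,
                                           beta_EO_direct = 0.1, seed = r))
    est <- mr_ml(rows)
    hits <- hits + (est$ci_low <= 0.1 && 0.1 <= est$ci_high)
  }
  # binomial 99% interval around 0.95 at 200 reps: (0.905, 0.985)
  expect_gt(hits / reps, 0.905)
  expect_lt(hits / reps, 0.985)
})

test_that("weighted median interpolates cumulative weights as specified", {
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), c(1, 1, 1)), 0.2)
  # hand-worked interpolation oracle: 0.1 + 0.1*(0.5-0.25)/(0.625-0.25)
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), c(0.5, 0.25, 0.25)),
               0.1666667, tolerance = 1e-6)
  # invariant to input order
  expect_equal(weighted_median(c(0.3, 0.1, 0.2), c(0.25, 0.5, 0.25)),
               0.1666667, tolerance = 1e-6)
})

test_that("the weighted-median estimator resists <50% invalid weight", {
  # 49% of the weight sits on SNPs whose ratios are shifted +1: the weighted
  # median must stay near the valid cluster while IVW is dragged toward the
  # invalid one
  set.seed(11)
  n <- 200
  gamma <- rep(0.2, n)   # equal weights, so the invalid share is exact
  sx <- 0.01; sy <- 0.005
  by_true <- 0.1 * gamma
  shifted <- seq_len(floor(0.49 * n))
  by_true[shifted] <- by_true[shifted] + 1 * gamma[shifted]
  rows <- make_rows(bx = rnorm(n, gamma, sx), by = rnorm(n, by_true, sy),
                    sx = sx, sy = sy)
  est <- mr_weighted_median(rows, n_boot = 300, seed = 1)
  ivw <- mr_ivw(rows)
  expect_lt(abs(est$beta - 0.1), 0.1)          # within 10% of the +1 shift
  expect_gt(abs(ivw$beta - 0.1), 3 * abs(est$beta - 0.1))
  # and the estimate is order-invariant
  perm <- sample(n)
  est2 <- mr_weighted_median(rows[perm, ], n_boot = 300, seed = 1)
  expect_equal(est2$beta, est$beta, tolerance = 1e-12)
})

test_that("Egger recovers an exact linear relation with intercept", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  rows <- make_rows(bx = bx, by = 0.05 + 0.3 * bx, sx = 0.01, sy = 0.01)
  est <- mr_egger(rows)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$extras$intercept, 0.05, tolerance = 1e-10)
  expect_equal(est$extras$Q, 0, tolerance = 1e-16)
  expect_error(mr_egger(rows[1:2, ]), "at least 3")
})

test_that("the Egger intercept detects directional pleiotropy (InSIDE)", {
  # mean pleiotropic effect 0.05 on every SNP, independent of gamma
  set.seed(5)
  n <- 100
  gamma <- abs(rnorm(n, 0.15, 0.05))
  sx <- 0.005; sy <- 0.01
  alpha <- rnorm(n, 0.05, 0.02)
  rows <- make_rows(bx = rnorm(n, gamma, sx),
                    by = rnorm(n, 0.2 * gamma + alpha, sy), sx = sx, sy = sy)
  est <- mr_egger(rows)
  expect_lt(abs(est$extras$intercept - 0.05), 2 * est$extras$intercept_se)
  expect_lt(est$extras$intercept_p, 0.05)
})

test_that("estimators are equivariant under exposure rescaling", {
  rows <- random_rows(30, beta = 0.2, seed = 13)
  scaled <- rows
  c_ <- 2.5
  scaled$beta_exp <- rows$beta_exp * c_
  scaled$se_exp <- rows$se_exp * c_
  for (f in list(mr_ivw, mr_ml, mr_egger, mr_divw,
                 function(x) mr_weighted_median(x, n_boot = 50, seed = 2),
                 function(x) mr_raps(x, loss = "l2"))) {
    expect_equal(f(scaled)$beta, f(rows)$beta / c_, tolerance = 1e-6)
  }
})
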