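# Multivariable MR: set construction, IVW, Egger.

# rows with two exposures and known conditional effects
make_mvmr_rows <- function(n, b1 = 0.3, b2 = 0.5, seed = 1, sy = 0.01,
                           exact = FALSE) {
  set.seed(seed)
  g1 <- rnorm(n, 0, 0.1)
  g2 <- rnorm(n, 0, 0.1)
  y <- b1 * g1 + b2 * g2
  if (!exact) y <- rnorm(n, y, sy)
  data.frame(snp_id = sprintf("rs%03d", seq_len(n)),
             beta_e1 = g1, se_e1 = 0.01, pval_e1 = 1e-8,
             beta_e2 = g2, se_e2 = 0.01, pval_e2 = 1e-8,
             beta_out = y, se_out = sy, stringsAsFactors = FALSE)
}

test_that("multivariable IVW recovers exact linear structure and the oracle", {
  rows <- make_mvmr_rows(30, exact = TRUE)
  fit <- mvmr_ivw(rows)
  expect_equal(unname(vapply(fit$estimates, `[[`, numeric(1), "beta")),
               c(0.3, 0.5), tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-16)

  # weighted multivariable least-squares oracle on a noisy instance
  rows2 <- make_mvmr_rows(40, seed = 2)
  fit2 <- mvmr_ivw(rows2)
  oracle <- lm(beta_out ~ 0 + beta_e1 + beta_e2, data = rows2,
               weights = 1 / rows2$se_out^2)
  expect_equal(unname(vapply(fit2$estimates, `[[`, numeric(1), "beta")),
               unname(coef(oracle)), tolerance = 1e-10)
  # fixed-effects SEs from the weighted design
  V <- solve(crossprod(as.matrix(rows2[c("beta_e1", "beta_e2")]) /
                         rows2$se_out))
  infl <- max(1, sqrt(fit2$Q / (40 - 2)))
  expect_equal(unname(vapply(fit2$estimates, `[[`, numeric(1), "se")),
               unname(sqrt(diag(V))) * infl, tolerance = 1e-10)
})

test_that("a second exposure carrying no signal leaves the first coefficient
           at its univariable IVW value", {
  # beta_e2 orthogonalized against beta_e1 in the weighted metric: the
  # normal equations then decouple and the e1 coefficient equals
  # univariable IVW exactly
  rows <- make_mvmr_rows(30, b1 = 0.25, b2 = 0, seed = 3)
  w <- 1 / rows$se_out^2
  rows$beta_e2 <- rows$beta_e2 -
    rows$beta_e1 * sum(w * rows$beta_e1 * rows$beta_e2) /
    sum(w * rows$beta_e1^2)
  fit <- mvmr_ivw(rows)
  uni <- mr_ivw(data.frame(beta_exp = rows$beta_e1, se_exp = rows$se_e1,
                           beta_out = rows$beta_out, se_out = rows$se_out))
  expect_equal(unname(fit$estimates[[1]]$beta), uni$beta,
               tolerance = 1e-10)
})

test_that("MVMR estimates are equivariant under per-exposure rescaling", {
  rows <- make_mvmr_rows(30, seed = 4)
  fit <- mvmr_ivw(rows)
  scaled <- rows
  scaled$beta_e1 <- rows$beta_e1 * 3
  scaled$se_e1 <- rows$se_e1 * 3
  fit2 <- mvmr_ivw(scaled)
  expect_equal(fit2$estimates[[1]]$beta, fit$estimates[[1]]$beta / 3,
               tolerance = 1e-10)
  expect_equal(fit2$estimates[[2]]$beta, fit$estimates[[2]]$beta,
               tolerance = 1e-10)
})

test_that("multivariable Egger recovers slopes, intercept and pleiotropy", {
  rows <- make_mvmr_rows(30, exact = TRUE, seed = 5)
  # orient rows on exposure 1 the way the fitter will, then add an exact
  # intercept on the oriented scale
  flip <- rows$beta_e1 < 0
  rows$beta_out <- rows$beta_out +
    ifelse(flip, -0.04, 0.04)
  fit <- mvmr_egger(rows, orient_on = 1)
  expect_equal(fit$intercept, 0.04, tolerance = 1e-10)
  expect_equal(unname(vapply(fit$estimates, `[[`, numeric(1), "beta")),
               c(0.3, 0.5), tolerance = 1e-10)

  # planted directional pleiotropy is picked up by the intercept
  set.seed(6)
  rows2 <- make_mvmr_rows(80, seed = 6, sy = 0.005)
  flip2 <- rows2$beta_e1 < 0
  pleio <- rnorm(80, 0.03, 0.005)
  rows2$beta_out <- rows2$beta_out + ifelse(flip2, -pleio, pleio)
  fit2 <- mvmr_egger(rows2, orient_on = 1)
  expect_lt(abs(fit2$intercept - 0.03), 2 * fit2$intercept_se)
  expect_lt(fit2$intercept_p, 0.05)

  # without directional pleiotropy, the orientation choice is immaterial to
  # the slopes (it only redefines what the intercept averages over)
  rows3 <- make_mvmr_rows(40, seed = 7, exact = TRUE)
  fa <- mvmr_egger(rows3, orient_on = 1)
  fb <- mvmr_egger(rows3, orient_on = 2)
  expect_equal(unname(vapply(fa$estimates, `[[`, numeric(1), "beta")),
               unname(vapply(fb$estimates, `[[`, numeric(1), "beta")),
               tolerance = 1e-8)
})

test_that("mvmr set construction unions, re-clumps and aligns to the outcome", {
  # disjoint instrument sets: union of sizes
  sim <- simulate_gwas_triplet(sim_config(n_snps = 25, n_snps_med = 20,
                                          n_snps_out = 0, mean_f = 150,
                                          seed = 71))
  m <- build_mvmr_set(list(sim$exposure, sim$mediator), sim$outcome,
                      sim$panel)
  expect_s3_class(m, "mvmr_set")
  # both exposure- and mediator-role SNPs contribute instruments
  roles <- sim$truth$role[match(m$rows$snp_id, sim$truth$snp_id)]
  expect_true(all(c("exp", "med") %in% roles))
  fit <- mvmr_ivw(m)
  # conditional effect of the mediator on the outcome is beta_MO
  expect_lt(abs(fit$estimates[["mediator"]]$beta - 0.1),
            3 * fit$estimates[["mediator"]]$se)
  # and of the exposure, the direct effect
  expect_lt(abs(fit$estimates[["exposure"]]$beta - 0.15),
            3 * fit$estimates[["exposure"]]$se)

  # identical exposures: collinear design is refused
  expect_error(build_mvmr_set(list(sim$exposure, sim$exposure),
                              sim$outcome, sim$panel),
               "collinear|rank")
})

test_that("joint re-clumping equals a brute-force joint clump", {
  sim <- simulate_gwas_triplet(sim_config(n_snps = 24, n_snps_med = 12,
                                          n_snps_out = 0, mean_f = 200,
                                          ld_block_size = 4,
                                          ld_within_r2 = 0.64, seed = 72))
  m <- build_mvmr_set(list(sim$exposure, sim$mediator), sim$outcome,
                      sim$panel)
  kept <- m$rows$snp_id
  # no retained pair is dependent in the panel
  idx <- match(kept, sim$panel$snp_ids)
  off <- sim$panel$r2[idx, idx]; diag(off) <- 0
  expect_lt(max(off), 0.001 + 1e-12)
})
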