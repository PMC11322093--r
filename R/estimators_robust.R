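# Pleiotropy-robust and weak-instrument-robust estimators.

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Three parts. (a) Global test: the observed residual sum of squares
#' `RSS = sum_j (Gamma_j - beta_{-j} * gamma_j)^2 / sigma_Gamma_j^2`, with
#' `beta_{-j}` the leave-one-out IVW estimate, is compared with its null
#' distribution built from `n_sim` parametric simulations of the summary
#' statistics under the no-pleiotropy model; the global p is the fraction of
#' simulated RSS at or above the observed one. (b) Outlier test: each SNP's
#' simulated residual distribution gives a per-SNP p, Bonferroni-corrected
#' over the number of SNPs; SNPs below `outlier_alpha` are flagged.
#' (c) Corrected estimate: IVW after removing flagged outliers; a distortion
#' test compares the raw-vs-corrected shift against removals of random
#' subsets of the same size.
#'
#' @inheritParams mr_ivw
#' @param n_sim number of parametric simulations for the null distribution
#'   (default 1000).
#' @param outlier_alpha significance level for the Bonferroni-corrected
#'   per-SNP outlier test (default 0.05).
#' @param n_perm permutations for the distortion test (default 500).
#' @param seed optional RNG seed.
#' @return an [mr_estimate][new_mr_estimate] (the outlier-corrected IVW when
#'   outliers are flagged, otherwise the raw IVW); `extras` carries
#'   `global_rss`, `global_p`, `outlier_p` (per-SNP, Bonferroni-corrected),
#'   `outliers` (SNP indices), `outlier_snps`, `raw` (the uncorrected
#'   estimate), and `distortion_p`.
#' @export
mr_presso <- function(x, n_sim = 1000, outlier_alpha = 0.05, n_perm = 500,
                      seed = NULL) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 4, "MR-PRESSO")
  if (!is.numeric(n_sim) || n_sim < 1) {
    stop("n_sim must be a positive integer", call. = FALSE)
  }
  bx <- rows$beta_exp; by <- rows$beta_out
  sx <- rows$se_exp; sy <- rows$se_out
  sy2 <- sy^2

  loo_beta <- function(bx, by) {
    sn <- sum(bx * by / sy2); sd_ <- sum(bx^2 / sy2)
    (sn - bx * by / sy2) / (sd_ - bx^2 / sy2)
  }
  b_loo <- loo_beta(bx, by)
  resid2_obs <- (by - b_loo * bx)^2 / sy2
  rss_obs <- sum(resid2_obs)

  with_seed(seed, {
    resid2_sim <- matrix(0, n_sim, n)
    for (s in seq_len(n_sim)) {
      bxs <- rnorm(n, bx, sx)
      bys <- rnorm(n, b_loo * bx, sy)
      bl <- loo_beta(bxs, bys)
      resid2_sim[s, ] <- (bys - bl * bxs)^2 / sy2
    }
    rss_sim <- rowSums(resid2_sim)
    global_p <- mean(rss_sim >= rss_obs)
    outlier_p <- pmin(1, colMeans(sweep(resid2_sim, 2, resid2_obs, ">=")) * n)
    outliers <- which(outlier_p < outlier_alpha)

    raw <- mr_ivw(rows)
    distortion_p <- NA_real_
    if (length(outliers) > 0 && n - length(outliers) >= 2) {
      est <- mr_ivw(rows[-outliers, , drop = FALSE])
      obs_shift <- abs(est$beta - raw$beta)
      shifts <- replicate(n_perm, {
        drop <- sample.int(n, length(outliers))
        abs(mr_ivw(rows[-drop, , drop = FALSE])$beta - raw$beta)
      })
      distortion_p <- mean(shifts >= obs_shift)
    } else {
      est <- raw
      outliers <- integer(0)
    }
    out <- new_mr_estimate(
      "MR-PRESSO", est$beta, est$se, est$n_snp, pval = est$pval,
      extras = list(global_rss = rss_obs, global_p = global_p,
                    outlier_p = outlier_p, outliers = outliers,
                    outlier_snps = if ("snp_id" %in% names(rows))
                      rows$snp_id[outliers] else as.character(outliers),
                    raw = raw, distortion_p = distortion_p,
                    n_sim = n_sim))
    out
  })
}

#' Debiased IVW (dIVW)
#'
#' IVW's denominator `sum(gamma^2/sigma_Gamma^2)` is biased upward by the
#' sampling error of the SNP-exposure effects; dIVW subtracts it:
#' `beta = sum(gamma*Gamma/sigma_Gamma^2) /
#' sum((gamma^2 - sigma_gamma^2)/sigma_Gamma^2)`, removing weak-instrument
#' bias. The SE comes from the method's sandwich variance. Reduces to IVW
#' exactly when all `sigma_gamma = 0`.
#'
#' @inheritParams mr_ivw
#' @return an [mr_estimate][new_mr_estimate].
#' @export
mr_divw <- function(x) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 2, "dIVW")
  bx <- rows$beta_exp; by <- rows$beta_out
  sx2 <- rows$se_exp^2; sy2 <- rows$se_out^2
  denom <- sum((bx^2 - sx2) / sy2)
  if (denom <= 0) {
    stop("dIVW denominator non-positive: instruments too weak", call. = FALSE)
  }
  beta <- sum(bx * by / sy2) / denom
  # first-order variance of the estimating function sum[(gamma_hat*Gamma_hat
  # - beta*(gamma_hat^2 - sigma_gamma^2))/sigma_Gamma^2], scaled by denom^-2
  vnum <- sum((bx^2 * sy2 + beta^2 * bx^2 * sx2 + sx2 * sy2 +
                 2 * beta^2 * sx2^2) / sy2^2)
  se <- sqrt(vnum) / denom
  new_mr_estimate("dIVW", beta, se, n, extras = list(denominator = denom))
}

#' Contamination-mixture (ConMix) estimate
#'
#' Each SNP's Wald ratio contributes, at every candidate causal effect on a
#' grid, the larger of a valid-instrument likelihood `N(beta, se_j^2)` and an
#' invalid-instrument likelihood `N(0, se_j^2 + psi^2)`; the profile
#' log-likelihood is maximized over the grid and the 95% CI is the grid
#' region within `qchisq(0.95, 1)/2` of the maximum. `psi` is
#' `psi_mult` times the standard deviation of the ratio estimates.
#'
#' @inheritParams mr_ivw
#' @param psi_mult scale multiplier for the invalid-component standard
#'   deviation (default 1.5).
#' @param grid_n number of grid points (default 2001).
#' @param grid_range optional length-2 numeric; defaults to
#'   `[min(ratio) - 3*max(se), max(ratio) + 3*max(se)]`.
#' @return an [mr_estimate][new_mr_estimate]; `extras` carries the
#'   valid-SNP classification at the optimum and the grid used. A warning is
#'   issued when the confidence region is disjoint (multimodal likelihood);
#'   the reported CI is its range.
#' @export
mr_conmix <- function(x, psi_mult = 1.5, grid_n = 2001, grid_range = NULL) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "ConMix")
  wr <- wald_ratios(rows)
  psi <- psi_mult * stats::sd(wr$ratio)
  if (!is.finite(psi) || psi <= 0) psi <- psi_mult * max(wr$se)
  if (is.null(grid_range)) {
    grid_range <- c(min(wr$ratio) - 3 * max(wr$se),
                    max(wr$ratio) + 3 * max(wr$se))
  }
  if (grid_n < 3 || grid_range[2] <= grid_range[1]) {
    stop("degenerate ConMix grid", call. = FALSE)
  }
  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)

  ll_invalid <- dnorm(wr$ratio, 0, sqrt(wr$se^2 + psi^2), log = TRUE)
  # grid_n x n matrix of valid-component log-likelihoods
  ll_valid <- matrix(dnorm(rep(wr$ratio, each = grid_n),
                           mean = rep(grid, times = n),
                           sd = rep(wr$se, each = grid_n), log = TRUE),
                     nrow = grid_n)
  prof <- rowSums(pmax(ll_valid, matrix(ll_invalid, grid_n, n, byrow = TRUE)))
  imax <- which.max(prof)
  beta <- grid[imax]
  inside <- prof >= prof[imax] - qchisq(0.95, 1) / 2
  ci <- range(grid[inside])
  runs <- rle(inside)
  if (sum(runs$values) > 1) {
    warning("ConMix confidence region is disjoint; reporting its range",
            call. = FALSE)
  }
  se <- (ci[2] - ci[1]) / (2 * qnorm(0.975))
  valid <- ll_valid[imax, ] >= ll_invalid
  est <- new_mr_estimate("ConMix", beta, max(se, .Machine$double.eps), n,
                         extras = list(psi = psi, valid = valid,
                                       n_valid = sum(valid),
                                       grid_range = grid_range,
                                       grid_n = grid_n))
  est$ci_low <- ci[1]; est$ci_high <- ci[2]
  est
}

# Robust loss rho, score psi = rho', and its standard-normal moments:
# delta = E[psi(Z) Z] (overdispersion matching), c1 = E[psi'(Z)] and
# c2 = E[psi(Z)^2] (the efficiency factors of the asymptotic variance).
raps_rho <- function(loss, k) {
  gauss <- function(f) integrate(function(z) f(z) * dnorm(z),
                                 -Inf, Inf)$value
  out <- switch(loss,
    l2 = list(
      rho = function(t) t^2 / 2,
      psi = function(t) t,
      delta = 1, c1 = 1, c2 = 1),
    huber = list(
      rho = function(t) ifelse(abs(t) <= k, t^2 / 2,
                               k * abs(t) - k^2 / 2),
      psi = function(t) pmin(pmax(t, -k), k),
      delta = 2 * pnorm(k) - 1,
      c1 = 2 * pnorm(k) - 1,
      c2 = (2 * pnorm(k) - 1 - 2 * k * dnorm(k)) +
        2 * k^2 * pnorm(k, lower.tail = FALSE)),
    tukey = list(
      rho = function(t) ifelse(abs(t) < k,
                               k^2 / 6 * (1 - (1 - (t / k)^2)^3),
                               k^2 / 6),
      psi = function(t) ifelse(abs(t) < k, t * (1 - (t / k)^2)^2, 0),
      delta = NULL, c1 = NULL, c2 = NULL)
  )
  if (loss == "tukey") {
    psi <- out$psi
    out$delta <- gauss(function(z) psi(z) * z)
    out$c1 <- gauss(function(z) {
      ifelse(abs(z) < k, (1 - (z / k)^2) * (1 - 5 * (z / k)^2), 0)
    })
    out$c2 <- gauss(function(z) psi(z)^2)
  }
  out
}

#' Robust adjusted profile score (MR-RAPS)
#'
#' Solves the adjusted profile-score estimating equation
#' `sum_j psi(t_j) * d t_j / d beta = 0` with standardized residuals
#' `t_j = (Gamma_j - beta*gamma_j) / sqrt(sigma_Gamma_j^2 +
#' beta^2*sigma_gamma_j^2 + tau^2)`, jointly fitting an overdispersion
#' variance `tau^2 >= 0` so the robustified residual scale matches its
#' standard-normal expectation. Valid under many weak instruments; the Huber
#' and Tukey losses bound the influence of pleiotropic outliers. The SE is
#' the M-estimation sandwich.
#'
#' @inheritParams mr_ivw
#' @param loss `"huber"` (default), `"tukey"`, or `"l2"`.
#' @param k tuning constant of the loss (defaults: 1.345 Huber,
#'   4.685 Tukey).
#' @param overdispersion fit `tau^2` (default `TRUE`); `FALSE` fixes it at 0.
#' @return an [mr_estimate][new_mr_estimate]; `extras` carries `tau2` and
#'   the loss used.
#' @export
mr_raps <- function(x, loss = c("huber", "tukey", "l2"), k = NULL,
                    overdispersion = TRUE) {
  loss <- match.arg(loss)
  if (is.null(k)) k <- switch(loss, huber = 1.345, tukey = 4.685, l2 = NA)
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "MR-RAPS")
  bx <- rows$beta_exp; by <- rows$beta_out
  sx2 <- rows$se_exp^2; sy2 <- rows$se_out^2
  rob <- raps_rho(loss, k)

  tfun <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    list(t = (by - beta * bx) / sqrt(v), v = v)
  }
  # d t_j / d beta at fixed tau2
  dt_dbeta <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    (-bx * v - (by - beta * bx) * beta * sx2) / v^1.5
  }
  score_beta <- function(beta, tau2) {
    s <- tfun(beta, tau2)
    sum(rob$psi(s$t) * dt_dbeta(beta, tau2))
  }
  score_tau <- function(tau2, beta) {
    s <- tfun(beta, tau2)
    sum(rob$psi(s$t) * s$t - rob$delta)
  }
  # the score is the exact gradient of the bounded loss sum(rho(t_j)), and
  # it vanishes at +/- infinity, so the solution is found by minimizing the
  # loss on an interval around the IVW start (expanded while the optimum
  # sits on the boundary) rather than by root-hunting on the score
  loss_fun <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    sum(rob$rho((by - beta * bx) / sqrt(v)))
  }
  solve_beta <- function(tau2, start) {
    w <- max(1, 10 * abs(start))
    for (tries in 1:10) {
      opt <- optimize(loss_fun, c(start - w, start + w), tau2 = tau2,
                      tol = 1e-12)
      margin <- 1e-3 * w
      if (opt$minimum > start - w + margin &&
          opt$minimum < start + w - margin) {
        return(opt$minimum)
      }
      w <- w * 4
    }
    stop("MR-RAPS: profile-loss minimum not located (no interior optimum)",
         call. = FALSE)
  }

  beta <- mr_ivw(rows)$beta
  tau2 <- 0
  for (it in seq_len(50)) {
    beta_new <- solve_beta(tau2, beta)
    tau2_new <- tau2
    if (overdispersion) {
      if (score_tau(0, beta_new) <= 0) {
        tau2_new <- 0
      } else {
        hi <- max(sy2) * 10
        while (score_tau(hi, beta_new) > 0 && hi < 1e8) hi <- hi * 10
        tau2_new <- uniroot(score_tau, c(0, hi), beta = beta_new,
                            tol = 1e-12)$root
      }
    }
    done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
    beta <- beta_new; tau2 <- tau2_new
    if (done) break
  }

  # Model-based sandwich. The naive empirical sandwich on the profile score
  # underestimates the variance (the information identity fails for profile
  # scores), so the A and B expectations are evaluated under the fitted
  # model: A = c1 * I_p, B = c2 * I_p with I_p the profile information for
  # beta (the maximum-likelihood block inversion, with the fitted
  # overdispersion folded into the outcome variances), giving
  # Var = (c2 / c1^2) / I_p — the classical M-estimation efficiency factor
  # on the ML variance, exact for the l2 loss.
  se_base <- ml_beta_se(beta, bx, by, sx2, sy2 + tau2)
  if (!is.finite(se_base)) {
    stop("MR-RAPS: degenerate curvature at the solution", call. = FALSE)
  }
  se <- se_base * sqrt(rob$c2) / rob$c1
  new_mr_estimate("MR-RAPS", beta, se, n,
                  extras = list(tau2 = tau2, loss = loss, k = k))
}

# Constrained ML at a fixed number K of invalid instruments: iterate
# selection of the K SNPs with the largest valid-model likelihood cost and
# profile-ML on the remaining valid set.
cml_fit_k <- function(K, bx, by, sx2, sy2, start, maxit = 100, tol = 1e-8) {
  n <- length(bx)
  beta <- start
  invalid <- integer(0)
  for (it in seq_len(maxit)) {
    g <- (bx / sx2 + beta * by / sy2) / (1 / sx2 + beta^2 / sy2)
    cost <- (bx - g)^2 / (2 * sx2) + (by - beta * g)^2 / (2 * sy2)
    invalid_new <- if (K > 0) order(cost, decreasing = TRUE)[seq_len(K)] else
      integer(0)
    valid <- setdiff(seq_len(n), invalid_new)
    if (length(valid) < 2) return(NULL)
    nll_fun <- function(b) ml_profile_nll(b, bx[valid], by[valid],
                                          sx2[valid], sy2[valid])
    width <- max(1, 10 * abs(beta), diff(range(by / bx)))
    opt <- optimize(nll_fun, c(beta - width, beta + width), tol = 1e-10)
    conv <- setequal(invalid_new, invalid) && abs(opt$minimum - beta) < tol
    beta <- opt$minimum
    invalid <- invalid_new
    if (conv) {
      se <- ml_beta_se(beta, bx[valid], by[valid], sx2[valid], sy2[valid])
      if (!is.finite(se)) return(NULL)
      return(list(beta = beta, se = se, nll = opt$objective,
                  invalid = sort(invalid)))
    }
  }
  NULL  # no convergence at this K
}

#' Constrained maximum likelihood with model averaging (cML-MA)
#'
#' For each candidate number K of invalid instruments, constrained ML gives
#' exactly K SNPs a free pleiotropy offset (chosen iteratively by largest
#' likelihood gain) and maximizes the likelihood over the rest; per-K
#' estimates are combined with BIC-derived weights. The default is the
#' deterministic no-data-perturbation variant.
#'
#' @inheritParams mr_ivw
#' @param k_grid integer vector of candidate invalid counts; default
#'   `0:(n-2)`.
#' @param n_perturb number of data perturbations (default 0, the
#'   deterministic variant); when positive, the estimate and SE additionally
#'   average over perturbed copies of the summary statistics.
#' @param seed optional RNG seed (used only when `n_perturb > 0`).
#' @param n_sample GWAS sample size used in the BIC penalty `K*log(n_sample)`
#'   (the method's convention); defaults to the smaller of the median
#'   exposure/outcome sample sizes carried by the rows, falling back to
#'   `1e5` when the rows carry none.
#' @return an [mr_estimate][new_mr_estimate]; `extras` carries the BIC
#'   weights, the BIC-weighted invalid count, and the selected invalid set
#'   at the modal K.
#' @export
mr_cml_ma <- function(x, k_grid = NULL, n_perturb = 0, seed = NULL,
                      n_sample = NULL) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "cML-MA")
  if (is.null(k_grid)) k_grid <- 0:(n - 2)
  stopifnot(all(k_grid >= 0), all(k_grid <= n - 2))
  bx <- rows$beta_exp; by <- rows$beta_out
  sx2 <- rows$se_exp^2; sy2 <- rows$se_out^2
  if (is.null(n_sample)) {
    ns <- c(if ("n_exp" %in% names(rows)) stats::median(rows$n_exp),
            if ("n_out" %in% names(rows)) stats::median(rows$n_out))
    n_sample <- if (length(ns) && any(is.finite(ns)))
      min(ns, na.rm = TRUE) else 1e5
  }

  fit_once <- function(bx, by) {
    start <- mr_ivw(data.frame(beta_exp = bx, se_exp = sqrt(sx2),
                               beta_out = by, se_out = sqrt(sy2)))$beta
    fits <- lapply(k_grid, cml_fit_k, bx = bx, by = by, sx2 = sx2,
                   sy2 = sy2, start = start)
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      stop("cML-MA: no K in the grid converged", call. = FALSE)
    }
    if (!all(ok)) {
      warning("cML-MA: ", sum(!ok), " K value(s) failed to converge and were ",
              "omitted", call. = FALSE)
    }
    fits <- fits[ok]; ks <- k_grid[ok]
    bic <- vapply(fits, function(f) 2 * f$nll, numeric(1)) +
      ks * log(n_sample)
    w <- exp(-(bic - min(bic)) / 2)
    w <- w / sum(w)
    betas <- vapply(fits, `[[`, numeric(1), "beta")
    ses <- vapply(fits, `[[`, numeric(1), "se")
    beta <- sum(w * betas)
    se <- sqrt(sum(w * (ses^2 + (betas - beta)^2)))
    modal <- which.max(w)
    list(beta = beta, se = se, weights = w, ks = ks,
         invalid_count = sum(w * ks), invalid = fits[[modal]]$invalid)
  }

  if (n_perturb > 0) {
    res <- with_seed(seed, {
      fits <- replicate(n_perturb, {
        fit_once(rnorm(n, bx, sqrt(sx2)), rnorm(n, by, sqrt(sy2)))
      }, simplify = FALSE)
      betas <- vapply(fits, `[[`, numeric(1), "beta")
      ses <- vapply(fits, `[[`, numeric(1), "se")
      base <- fit_once(bx, by)
      base$beta <- mean(betas)
      base$se <- sqrt(mean(ses^2) + stats::var(betas))
      base
    })
  } else {
    res <- fit_once(bx, by)
  }
  new_mr_estimate(
    "cML-MA", res$beta, res$se, n,
    extras = list(bic_weights = stats::setNames(res$weights,
                                                paste0("K=", res$ks)),
                  invalid_count = res$invalid_count,
                  invalid = res$invalid, n_perturb = n_perturb)
  )
}

#' Run a set of MR estimators on one instrument set
#'
#' @inheritParams mr_ivw
#' @param methods character vector among `"ivw"`, `"ml"`, `"wm"`, `"egger"`,
#'   `"presso"`, `"divw"`, `"conmix"`, `"raps"`, `"cml"`.
#' @param seed optional seed shared by the stochastic methods (weighted
#'   median bootstrap, MR-PRESSO simulations).
#' @param presso_n_sim simulations for MR-PRESSO.
#' @param wm_n_boot bootstrap resamples for the weighted median.
#' @return named list of [mr_estimate][new_mr_estimate] objects; a method
#'   that errors (e.g. too few SNPs) is returned as `NULL` with a warning.
#' @export
mr_run <- function(x, methods = c("ivw", "ml", "wm", "egger", "presso",
                                  "divw", "conmix", "raps", "cml"),
                   seed = NULL, presso_n_sim = 1000, wm_n_boot = 1000) {
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(
    ivw = function() mr_ivw(x),
    ml = function() mr_ml(x),
    wm = function() mr_weighted_median(x, n_boot = wm_n_boot, seed = seed),
    egger = function() mr_egger(x),
    presso = function() mr_presso(x, n_sim = presso_n_sim, seed = seed),
    divw = function() mr_divw(x),
    conmix = function() mr_conmix(x),
    raps = function() mr_raps(x),
    cml = function() mr_cml_ma(x)
  )
  out <- lapply(methods, function(m) {
    tryCatch(runners[[m]](), error = function(e) {
      warning(sprintf("%s failed: %s", m, conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  names(out) <- methods
  out
}

#' Tabulate MR estimates in report form
#'
#' One row per method with the columns screening reports print: method,
#' number of SNPs, p-value, beta and its 95% CI.
#'
#' @param estimates list of [mr_estimate][new_mr_estimate] objects (e.g.
#'   from [mr_run()]); `NULL` entries are skipped.
#' @return a data frame.
#' @export
mr_table <- function(estimates) {
  rows <- lapply(Filter(Negate(is.null), estimates), as.data.frame)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
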