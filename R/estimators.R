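# Core two-sample MR estimators. All take harmonized per-SNP rows (directly,
# or inside a harmonized_set / instrument_set) and return an mr_estimate.
# Notation per SNP j: gamma_j (beta_exp) with SE sigma_gamma_j, Gamma_j
# (beta_out) with SE sigma_Gamma_j.

#' Per-SNP Wald ratios
#'
#' The single-SNP causal estimate `Gamma_j / gamma_j` with first-order
#' standard error `sigma_Gamma_j / |gamma_j|`, plus the IVW weight
#' `gamma_j^2 / sigma_Gamma_j^2` (the inverse first-order ratio variance).
#'
#' @param x harmonized rows (data frame, `harmonized_set`, or
#'   `instrument_set`).
#' @return data frame with columns `snp_id` (if available), `ratio`, `se`,
#'   `weight`.
#' @export
wald_ratios <- function(x) {
  rows <- mr_input_rows(x)
  if (any(rows$beta_exp == 0)) {
    stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  }
  data.frame(
    snp_id = if ("snp_id" %in% names(rows)) rows$snp_id else
      as.character(seq_len(nrow(rows))),
    ratio = rows$beta_out / rows$beta_exp,
    se = rows$se_out / abs(rows$beta_exp),
    weight = rows$beta_exp^2 / rows$se_out^2,
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/sigma_Gamma^2`:
#' `beta = sum(gamma*Gamma/sigma_Gamma^2) / sum(gamma^2/sigma_Gamma^2)`.
#' The fixed-effects SE is `(sum(gamma^2/sigma_Gamma^2))^(-1/2)`; under
#' multiplicative random effects it is inflated by `max(1, sqrt(Q/(n-1)))`
#' where Q is Cochran's heterogeneity statistic. `"auto"` (the default)
#' applies random effects when `Q/(n-1) > 1`.
#'
#' @param x harmonized rows (data frame, `harmonized_set`, or
#'   `instrument_set`).
#' @param effects_model `"auto"`, `"fixed"`, or `"random"`.
#' @return an [mr_estimate][new_mr_estimate]; `extras` carries `Q`, `Q_df`,
#'   `Q_pval`, `se_fixed`, and the effects model applied.
#' @export
mr_ivw <- function(x, effects_model = c("auto", "fixed", "random")) {
  effects_model <- match.arg(effects_model)
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 2, "IVW")
  bx <- rows$beta_exp; by <- rows$beta_out; sy2 <- rows$se_out^2
  denom <- sum(bx^2 / sy2)
  beta <- sum(bx * by / sy2) / denom
  se_fixed <- 1 / sqrt(denom)
  q <- sum((by - beta * bx)^2 / sy2)
  q_df <- n - 1
  overdispersed <- q / q_df > 1
  model <- switch(effects_model,
                  auto = if (overdispersed) "random" else "fixed",
                  effects_model)
  se <- if (model == "random") se_fixed * max(1, sqrt(q / q_df)) else se_fixed
  new_mr_estimate(
    "IVW", beta, se, n,
    extras = list(Q = q, Q_df = q_df,
                  Q_pval = pchisq(q, q_df, lower.tail = FALSE),
                  se_fixed = se_fixed, effects_model = model)
  )
}

# Profile negative log-likelihood for the bivariate normal measurement model
# gamma_hat_j ~ N(gamma_j, sx_j^2), Gamma_hat_j ~ N(beta*gamma_j, sy_j^2),
# with the nuisance gamma_j profiled out in closed form.
ml_profile_nll <- function(beta, bx, by, sx2, sy2) {
  g <- (bx / sx2 + beta * by / sy2) / (1 / sx2 + beta^2 / sy2)
  sum((bx - g)^2 / (2 * sx2) + (by - beta * g)^2 / (2 * sy2))
}

# Observed-information SE for beta in the joint (beta, gamma_1..n) model,
# via block inversion of the (n+1)-dim Hessian.
ml_beta_se <- function(beta, bx, by, sx2, sy2) {
  g <- (bx / sx2 + beta * by / sy2) / (1 / sx2 + beta^2 / sy2)
  a <- sum(g^2 / sy2)
  cvec <- (2 * beta * g - by) / sy2
  d <- 1 / sx2 + beta^2 / sy2
  info <- a - sum(cvec^2 / d)
  if (info <= 0) return(NA_real_)
  1 / sqrt(info)
}

#' Maximum-likelihood estimate
#'
#' Maximizes the joint normal likelihood over the causal effect and the true
#' per-SNP exposure effects (`gamma_hat_j ~ N(gamma_j, sigma_gamma_j^2)`,
#' `Gamma_hat_j ~ N(beta*gamma_j, sigma_Gamma_j^2)`), starting from the IVW
#' estimate; the SE comes from the observed information. Unlike IVW, the
#' likelihood accounts for uncertainty in the SNP-exposure effects.
#'
#' @inheritParams mr_ivw
#' @return an [mr_estimate][new_mr_estimate].
#' @export
mr_ml <- function(x) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 2, "maximum likelihood")
  bx <- rows$beta_exp; by <- rows$beta_out
  sx2 <- rows$se_exp^2; sy2 <- rows$se_out^2
  start <- mr_ivw(rows)$beta
  width <- max(1, 10 * abs(start), diff(range(by / bx)))
  opt <- optimize(ml_profile_nll, interval = c(start - width, start + width),
                  bx = bx, by = by, sx2 = sx2, sy2 = sy2, tol = 1e-10)
  beta <- opt$minimum
  se <- ml_beta_se(beta, bx, by, sx2, sy2)
  if (!is.finite(se)) {
    stop("maximum-likelihood information matrix not positive definite",
         call. = FALSE)
  }
  new_mr_estimate("ML", beta, se, n, extras = list(nll = opt$objective))
}

#' Weighted-median estimate
#'
#' The weighted median of the per-SNP Wald ratios under normalized IVW
#' weights (see [weighted_median()]); consistent as long as at least half of
#' the weight comes from valid instruments. The SE is the standard deviation
#' of the estimate over `n_boot` parametric-bootstrap resamples of the
#' summary statistics.
#'
#' @inheritParams mr_ivw
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @return an [mr_estimate][new_mr_estimate].
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed = NULL) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "weighted median")
  wr <- wald_ratios(rows)
  beta <- weighted_median(wr$ratio, wr$weight)
  bx <- rows$beta_exp; by <- rows$beta_out
  sx <- rows$se_exp; sy <- rows$se_out
  se <- with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bxs <- rnorm(n, bx, sx)
      bys <- rnorm(n, by, sy)
      ok <- bxs != 0
      est[b] <- weighted_median(bys[ok] / bxs[ok], bxs[ok]^2 / sy[ok]^2)
    }
    stats::sd(est)
  })
  new_mr_estimate("WM", beta, se, n, extras = list(n_boot = n_boot))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects *with* an
#' intercept, weights `1/sigma_Gamma^2`, on rows oriented so
#' `beta_exp >= 0`. The slope is the causal estimate (consistent under the
#' InSIDE assumption even with directional pleiotropy); the intercept and
#' its p-value are the horizontal-pleiotropy test. SEs use the
#' multiplicative random-effects inflation `max(1, sqrt(Q_egger/(n-2)))`.
#'
#' @inheritParams mr_ivw
#' @return an [mr_estimate][new_mr_estimate]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_p`, `Q`, `Q_df`, `Q_pval`.
#' @export
mr_egger <- function(x) {
  rows <- mr_input_rows(x)
  n <- nrow(rows)
  check_n_snp(n, 3, "MR-Egger")
  # orient defensively; harmonize() normally did this already
  flip <- rows$beta_exp < 0
  bx <- abs(rows$beta_exp)
  by <- ifelse(flip, -rows$beta_out, rows$beta_out)
  w <- 1 / rows$se_out^2
  fit <- lm(by ~ bx, weights = w)
  q <- sum(w * stats::residuals(fit)^2)
  infl <- max(1, sqrt(q / (n - 2)))
  # fixed-effects SEs from the weighted design directly (robust to an exact
  # fit, where the residual scale is zero)
  X <- cbind(1, bx)
  se_fixed <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
  beta <- unname(coef(fit)["bx"])
  se <- se_fixed[2] * infl
  b0 <- unname(coef(fit)["(Intercept)"])
  b0_se <- se_fixed[1] * infl
  new_mr_estimate(
    "MR-Egger", beta, se, n,
    extras = list(intercept = b0, intercept_se = b0_se,
                  intercept_p = two_sided_p(b0, b0_se),
                  Q = q, Q_df = n - 2,
                  Q_pval = pchisq(q, n - 2, lower.tail = FALSE))
  )
}
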