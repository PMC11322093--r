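# Multivariable MR: the conditional effect of each exposure on the outcome
# given the others, from summary statistics harmonized to a shared allele
# reference.

#' Build a multivariable MR set
#'
#' Instruments are the union of each exposure's post-filter, post-clump
#' instruments, re-clumped jointly (the smallest p-value across exposures
#' decides clump winners), restricted to SNPs present in every exposure and
#' in the outcome, and aligned to a common effect allele per SNP. Rows are
#' not orientation-flipped; [mvmr_egger()] orients on a chosen exposure.
#'
#' @param exposures list of [summary_stats] (>= 2 for adjustment; generic k
#'   supported).
#' @param outcome a [summary_stats].
#' @param panel an [ld_panel].
#' @param config an [instrument_config()].
#' @param selection `"union"` (default) or `"intersection"` of the
#'   exposures' instrument candidates.
#' @return an object of class `mvmr_set`: list with `exposure_ids`,
#'   `outcome_id`, and `rows` — a data frame with `snp_id`, alleles,
#'   `beta_out`, `se_out`, and per-exposure columns `beta_e<i>`, `se_e<i>`,
#'   `pval_e<i>`.
#' @export
build_mvmr_set <- function(exposures, outcome, panel,
                           config = instrument_config(),
                           selection = c("union", "intersection")) {
  selection <- match.arg(selection)
  stopifnot(length(exposures) >= 1,
            all(vapply(exposures, inherits, logical(1), "summary_stats")))
  k <- length(exposures)

  # per-exposure candidates: significance/MAF filter + per-exposure clump
  cand <- lapply(exposures, function(ex) {
    sig <- filter_significance(ex, p_max = config$p_max,
                               maf_min = config$maf_min,
                               strict_maf = config$strict_maf)
    clump(sig, panel, r2_max = config$r2_max, window_kb = config$window_kb)
  })
  ids <- lapply(cand, function(s) s$records$snp_id)
  pool <- if (selection == "union") Reduce(union, ids) else
    Reduce(intersect, ids)
  # every MVMR row needs all exposures and the outcome measured
  pool <- Reduce(intersect, c(lapply(exposures,
                                     function(e) e$records$snp_id),
                              list(outcome$records$snp_id, pool)))
  if (length(pool) < k + 1) {
    stop("too few shared SNPs for multivariable MR", call. = FALSE)
  }

  # joint re-clump with min-p across exposures
  minp <- do.call(pmin, lapply(exposures, function(e) {
    e$records$pval[match(pool, e$records$snp_id)]
  }))
  joint <- summary_stats(
    data.frame(snp_id = pool, effect_allele = "A", other_allele = "G",
               beta = 1, se = 1, pval = minp, stringsAsFactors = FALSE),
    trait_id = "joint")
  joint <- clump(joint, panel, r2_max = config$r2_max,
                 window_kb = config$window_kb)
  pool <- joint$records$snp_id

  # align every trait to the outcome's allele reference (orientation off so
  # all traits share the same reference)
  sub_outcome <- outcome
  sub_outcome$records <- outcome$records[
    outcome$records$snp_id %in% pool, , drop = FALSE]
  aligned <- lapply(exposures, function(ex) {
    harmonize(sub_outcome, ex,
              palindrome_maf_max = config$palindrome_maf_max,
              orient = FALSE)$rows
  })
  shared <- Reduce(intersect, lapply(aligned, `[[`, "snp_id"))
  if (length(shared) < k + 1) {
    stop("too few harmonizable SNPs for multivariable MR", call. = FALSE)
  }
  base <- aligned[[1]][match(shared, aligned[[1]]$snp_id), ]
  rows <- data.frame(snp_id = shared, chrom = base$chrom, pos = base$pos,
                     effect_allele = base$effect_allele,
                     other_allele = base$other_allele,
                     beta_out = base$beta_exp, se_out = base$se_exp,
                     stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    a <- aligned[[i]][match(shared, aligned[[i]]$snp_id), ]
    rows[[paste0("beta_e", i)]] <- a$beta_out
    rows[[paste0("se_e", i)]] <- a$se_out
    rows[[paste0("pval_e", i)]] <- a$pval_out
  }
  rownames(rows) <- NULL

  X <- as.matrix(rows[paste0("beta_e", seq_len(k))])
  if (qr(X)$rank < k) {
    stop("collinear exposure effects: multivariable design is rank-deficient",
         call. = FALSE)
  }
  structure(
    list(exposure_ids = vapply(exposures, `[[`, character(1), "trait_id"),
         outcome_id = outcome$trait_id,
         rows = rows),
    class = "mvmr_set"
  )
}

# Weighted multivariable regression shared by mvmr_ivw / mvmr_egger.
mvmr_wls <- function(X, y, w, n_snp, labels, df_resid) {
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  beta <- drop(V %*% (XtW %*% y))
  resid <- y - drop(X %*% beta)
  q <- sum(w * resid^2)
  infl <- max(1, sqrt(q / df_resid))
  se <- sqrt(diag(V)) * infl
  list(beta = stats::setNames(beta, labels),
       se = stats::setNames(se, labels),
       Q = q, Q_df = df_resid,
       Q_pval = pchisq(q, df_resid, lower.tail = FALSE))
}

#' Multivariable IVW
#'
#' Weighted multivariable regression of outcome effects on all exposures'
#' effects without intercept, weights `1/se_out^2`; each coefficient is that
#' exposure's conditional (adjusted) causal effect. SEs use multiplicative
#' random-effects inflation as in univariable IVW. Conditional F statistics
#' (instrument strength of each exposure given the others, computed from the
#' weighted residuals of regressing its effects on the other exposures') are
#' reported as a diagnostic.
#'
#' @param m an `mvmr_set` from [build_mvmr_set()], or a data frame with
#'   `beta_out`, `se_out` and `beta_e<i>`/`se_e<i>` columns.
#' @return list with `estimates` (named list of
#'   [mr_estimate][new_mr_estimate], one per exposure), `Q`, `Q_df`,
#'   `Q_pval`, `conditional_f`.
#' @export
mvmr_ivw <- function(m) {
  rows <- if (inherits(m, "mvmr_set")) m$rows else m
  labels <- if (inherits(m, "mvmr_set")) m$exposure_ids else NULL
  bcols <- grep("^beta_e[0-9]+$", names(rows), value = TRUE)
  k <- length(bcols)
  n <- nrow(rows)
  if (is.null(labels)) labels <- bcols
  if (n <= k) stop("multivariable IVW needs more SNPs than exposures",
                   call. = FALSE)
  X <- as.matrix(rows[bcols])
  w <- 1 / rows$se_out^2
  fit <- mvmr_wls(X, rows$beta_out, w, n, labels, df_resid = n - k)

  cond_f <- vapply(seq_len(k), function(j) {
    se_j <- rows[[sub("beta", "se", bcols[j])]]
    if (k == 1) return(mean((X[, j] / se_j)^2))
    other <- X[, -j, drop = FALSE]
    r <- stats::lm.wfit(other, X[, j], w = 1 / se_j^2)$residuals
    sum(r^2 / se_j^2) / (n - k + 1)
  }, numeric(1))

  ests <- lapply(seq_len(k), function(j) {
    new_mr_estimate(paste0("MVMR-IVW[", labels[j], "]"),
                    fit$beta[j], fit$se[j], n,
                    extras = list(Q = fit$Q, Q_pval = fit$Q_pval,
                                  conditional_f = cond_f[j]))
  })
  names(ests) <- labels
  list(estimates = ests, Q = fit$Q, Q_df = fit$Q_df, Q_pval = fit$Q_pval,
       conditional_f = stats::setNames(cond_f, labels))
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] but with an intercept, on rows oriented so the chosen
#' exposure's effects are non-negative; the intercept and its p-value test
#' directional pleiotropy in the multivariable model.
#'
#' @inheritParams mvmr_ivw
#' @param orient_on index (or trait id) of the exposure whose effects are
#'   made non-negative (default 1).
#' @return as [mvmr_ivw()], plus `intercept`, `intercept_se`, `intercept_p`.
#' @export
mvmr_egger <- function(m, orient_on = 1) {
  rows <- if (inherits(m, "mvmr_set")) m$rows else m
  labels <- if (inherits(m, "mvmr_set")) m$exposure_ids else NULL
  bcols <- grep("^beta_e[0-9]+$", names(rows), value = TRUE)
  k <- length(bcols)
  n <- nrow(rows)
  if (is.null(labels)) labels <- bcols
  if (is.character(orient_on)) orient_on <- match(orient_on, labels)
  if (n <= k + 1) stop("multivariable Egger needs more SNPs than exposures + 1",
                       call. = FALSE)
  flip <- rows[[bcols[orient_on]]] < 0
  X <- as.matrix(rows[bcols])
  y <- rows$beta_out
  X[flip, ] <- -X[flip, , drop = FALSE]
  y[flip] <- -y[flip]
  Xi <- cbind(intercept = 1, X)
  w <- 1 / rows$se_out^2
  fit <- mvmr_wls(Xi, y, w, n, c("intercept", labels), df_resid = n - k - 1)
  ests <- lapply(seq_len(k), function(j) {
    new_mr_estimate(paste0("MVMR-Egger[", labels[j], "]"),
                    fit$beta[j + 1], fit$se[j + 1], n,
                    extras = list(Q = fit$Q, Q_pval = fit$Q_pval))
  })
  names(ests) <- labels
  list(estimates = ests,
       intercept = unname(fit$beta[1]), intercept_se = unname(fit$se[1]),
       intercept_p = two_sided_p(fit$beta[1], fit$se[1]),
       Q = fit$Q, Q_df = fit$Q_df, Q_pval = fit$Q_pval)
}
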