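# Internal helpers shared across modules.

# Two-sided normal p from an estimate and its SE; clamped into (0, 1].
two_sided_p <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# DNA complement for single-base alleles.
allele_complement <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

# A/T and C/G allele pairs cannot be strand-resolved from letters alone.
is_palindromic <- function(effect, other) {
  effect == allele_complement(other)
}

#' Weighted median of per-SNP estimates
#'
#' Sorts the estimates, computes cumulative-weight percentile positions
#' `p_j = (S_j - w_j/2) / S_n`, and linearly interpolates the estimate at
#' the 50th percentile. Used by [mr_weighted_median()].
#'
#' @param x numeric estimates.
#' @param w positive weights.
#' @return the weighted median (length-1 numeric).
#' @export
#' @examples
#' weighted_median(c(0.1, 0.2, 0.3), c(0.5, 0.25, 0.25))
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- cumsum(w)
  p <- (s - w / 2) / s[length(s)]
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  approx(p, x, xout = 0.5, ties = "ordered")$y
}

# Standard confidence bounds at the given level from a normal approximation.
ci_bounds <- function(beta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

#' @rdname mr_estimate
#' @param method method tag, e.g. `"IVW"`.
#' @param beta,se causal-effect estimate and its standard error.
#' @param n_snp number of instruments used.
#' @param pval two-sided p-value; computed from `beta/se` by normal
#'   approximation when `NULL`.
#' @param extras named list of method-specific diagnostics.
#' @export
new_mr_estimate <- function(method, beta, se, n_snp, pval = NULL,
                            extras = list()) {
  if (is.null(pval)) pval <- two_sided_p(beta, se)
  ci <- ci_bounds(beta, se)
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = ci[1], ci_high = ci[2], pval = pval,
         n_snp = n_snp, extras = extras),
    class = "mr_estimate"
  )
}

#' MR causal-effect estimate
#'
#' A single estimator's result: point estimate, standard error, 95%
#' confidence bounds, two-sided p-value, the number of instruments, and a
#' method-specific `extras` list (e.g. the Egger intercept test, MR-PRESSO
#' global p and outlier indices, the ConMix valid-SNP set).
#'
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @name mr_estimate
#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4g (95%% CI %.4g, %.4g), se = %.4g, p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$se, x$pval))
  invisible(x)
}

#' @rdname mr_estimate
#' @param row.names,optional passed through (unused).
#' @export
as.data.frame.mr_estimate <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

# Extract the harmonized per-SNP rows an estimator needs from any of the
# containers that carry them.
mr_input_rows <- function(x) {
  rows <- if (is.data.frame(x)) {
    x
  } else if (inherits(x, "instrument_set")) {
    x$harmonized$rows
  } else if (inherits(x, "harmonized_set")) {
    x$rows
  } else {
    stop("expected a data frame, harmonized_set or instrument_set",
         call. = FALSE)
  }
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("input rows lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows
}

# Consistent error for estimators that need more instruments than supplied.
check_n_snp <- function(n, min, method) {
  if (n < min) {
    stop(sprintf("%s requires at least %d SNPs (got %d)", method, min, n),
         call. = FALSE)
  }
}

# set.seed only when the caller supplied one, preserving the caller's RNG
# stream otherwise.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    )
  }
  expr
}
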