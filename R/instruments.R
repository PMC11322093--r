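# Instrumental-variable selection: significance/MAF filters, instrument
# strength, greedy LD clumping, outcome-association exclusion, and Steiger
# directionality filtering.

#' Significance and minor-allele-frequency filter
#'
#' Retains SNPs associated with the trait at `pval < p_max` and with
#' `min(eaf, 1 - eaf) >= maf_min`. Records lacking an allele frequency pass
#' the MAF filter with a warning unless `strict_maf` is set.
#'
#' @param ss a [summary_stats] object.
#' @param p_max association p-value threshold (default `5e-5`, the relaxed
#'   instrument threshold used when genome-wide-significant variants are
#'   scarce, as for microbial abundance traits).
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param strict_maf drop records lacking `eaf` (default `FALSE`).
#' @return a filtered [summary_stats] object; zero survivors raise a
#'   condition of class `netmr_empty_selection`.
#' @export
filter_significance <- function(ss, p_max = 5e-5, maf_min = 0.01,
                                strict_maf = FALSE) {
  stopifnot(inherits(ss, "summary_stats"))
  r <- ss$records
  keep_p <- r$pval < p_max
  maf <- pmin(r$eaf, 1 - r$eaf)
  keep_maf <- !is.na(maf) & maf >= maf_min
  if (anyNA(maf) && maf_min > 0) {
    if (strict_maf) {
      # missing frequency cannot demonstrate MAF >= maf_min
    } else {
      warning(sum(is.na(maf)), " record(s) lack EAF; passing the MAF filter",
              call. = FALSE)
      keep_maf[is.na(maf)] <- TRUE
    }
  } else if (maf_min == 0) {
    keep_maf[is.na(maf)] <- TRUE
  }
  keep <- keep_p & keep_maf
  if (!any(keep)) {
    stop(empty_selection_condition(
      sprintf("no SNPs pass p < %g and MAF >= %g for '%s'",
              p_max, maf_min, ss$trait_id)))
  }
  out <- ss
  out$records <- r[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

# Structured signal for an empty instrument selection: callers at pipeline
# level catch it and record "no instruments" instead of crashing.
empty_selection_condition <- function(message, provenance = NULL) {
  structure(
    class = c("netmr_empty_selection", "error", "condition"),
    list(message = message, call = NULL, provenance = provenance)
  )
}

#' Per-SNP F statistics and the weak-instrument flag
#'
#' F = (beta/se)^2 per SNP; a mean F at or below 10 flags the instrument set
#' as potentially weak.
#'
#' @param ss a [summary_stats] object, or a data frame carrying `beta_exp`
#'   and `se_exp` columns (a harmonized set's rows).
#' @return list with `per_snp_f` (named numeric), `mean_f`, and `weak_flag`
#'   (`TRUE` when `mean_f <= 10`).
#' @export
compute_f_statistics <- function(ss) {
  if (inherits(ss, "summary_stats")) {
    b <- ss$records$beta; s <- ss$records$se; id <- ss$records$snp_id
  } else {
    rows <- mr_input_rows(ss)
    b <- rows$beta_exp; s <- rows$se_exp; id <- rows$snp_id
  }
  f <- (b / s)^2
  names(f) <- id
  list(per_snp_f = f, mean_f = mean(f), weak_flag = mean(f) <= 10)
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining SNP with the smallest p-value and removes
#' all unselected SNPs on the same chromosome within `window_kb` kilobases
#' whose squared correlation with it exceeds `r2_max`. Ties on p-value are
#' broken by (chrom, pos, snp_id) lexicographic order. SNPs absent from the
#' panel are dropped (with a note in the result's `clump_report` attribute).
#'
#' @param ss a [summary_stats] object.
#' @param panel an [ld_panel] covering the candidate SNPs.
#' @param r2_max r² threshold above which two SNPs are dependent
#'   (default 0.001).
#' @param window_kb window in kilobases within which r² is considered
#'   (default 10000).
#' @return the clumped [summary_stats]; attribute `clump_report` lists
#'   `n_absent` and `n_pruned`.
#' @export
clump <- function(ss, panel, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(ss, "summary_stats"), inherits(panel, "ld_panel"))
  r <- ss$records
  in_panel <- r$snp_id %in% panel$snp_ids
  n_absent <- sum(!in_panel)
  r <- r[in_panel, , drop = FALSE]
  if (nrow(r) == 0) {
    stop(empty_selection_condition("no candidate SNPs present in LD panel"))
  }
  idx <- match(r$snp_id, panel$snp_ids)
  chrom <- panel$positions$chrom[idx]
  pos <- panel$positions$pos[idx]

  ord <- order(r$pval, chrom, pos, r$snp_id)
  active <- rep(TRUE, nrow(r))
  selected <- logical(nrow(r))
  for (i in ord) {
    if (!active[i]) next
    selected[i] <- TRUE
    active[i] <- FALSE
    near <- active & chrom == chrom[i] &
      abs(pos - pos[i]) <= window_kb * 1000 &
      panel$r2[idx, idx[i]] > r2_max
    active[near] <- FALSE
  }
  out <- ss
  out$records <- r[selected, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "clump_report") <- list(n_absent = n_absent,
                                    n_pruned = sum(!selected) )
  out
}

#' Exclude SNPs significantly associated with the outcome
#'
#' Removes harmonized rows whose outcome association reaches `pval_out <
#' p_max`, a guard against instruments acting primarily through the outcome
#' (reverse causation).
#'
#' @param h a [harmonize()] result.
#' @param p_max outcome association threshold (default `5e-5`).
#' @return the filtered `harmonized_set`; removed SNPs are appended to its
#'   `dropped` table with reason `"outcome-associated"`.
#' @export
exclude_outcome_associated <- function(h, p_max = 5e-5) {
  stopifnot(inherits(h, "harmonized_set"))
  bad <- !is.na(h$rows$pval_out) & h$rows$pval_out < p_max
  if (any(bad)) {
    h$dropped <- rbind(h$dropped,
                       data.frame(snp_id = h$rows$snp_id[bad],
                                  reason = "outcome-associated",
                                  stringsAsFactors = FALSE))
    h$rows <- h$rows[!bad, , drop = FALSE]
    rownames(h$rows) <- NULL
  }
  h
}

# Variance explained by one SNP from its p-value and sample size:
# r^2 = F / (F + n - 2) with F the 1-df F-quantile of that p. This route
# needs no variance model, so binary outcomes are handled identically.
r2_from_pn <- function(pval, n) {
  f <- qf(pval, 1, n - 2, lower.tail = FALSE)
  f / (f + n - 2)
}

#' Steiger directionality filter
#'
#' Retains SNPs that explain more variance in the exposure than in the
#' outcome, guarding against instruments acting through the outcome. The
#' variance explained is derived from (p-value, sample size); the report
#' carries a z-test of the difference of Fisher-transformed correlations for
#' two independent samples, and marks a SNP "uncertain" when that test's
#' p-value exceeds `alpha`. Uncertain SNPs are kept when the point
#' inequality favours the exposure unless `drop_uncertain` is set.
#'
#' @param h a [harmonize()] result.
#' @param n_exp,n_out sample sizes used where a row lacks its own `n`.
#' @param alpha level for the direction z-test (default 0.05).
#' @param drop_uncertain also drop SNPs whose direction test is
#'   non-significant (default `FALSE`).
#' @return list with `harmonized` (the filtered set) and `report` (per-SNP
#'   data frame: `snp_id`, `r2_exp`, `r2_out`, `direction`, `z`, `pval`,
#'   `uncertain`, `kept`).
#' @export
steiger_filter <- function(h, n_exp = NULL, n_out = NULL, alpha = 0.05,
                           drop_uncertain = FALSE) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- h$rows
  ne <- ifelse(is.na(r$n_exp), n_exp %||% NA, r$n_exp)
  no <- ifelse(is.na(r$n_out), n_out %||% NA, r$n_out)
  if (anyNA(ne) || anyNA(no)) {
    stop("sample sizes required for Steiger filtering", call. = FALSE)
  }
  if (any(ne <= 3) || any(no <= 3)) {
    stop("Steiger filtering needs sample sizes above 3", call. = FALSE)
  }
  r2e <- r2_from_pn(r$pval_exp, ne)
  r2o <- r2_from_pn(r$pval_out, no)
  z <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) /
    sqrt(1 / (ne - 3) + 1 / (no - 3))
  p <- 2 * pnorm(-abs(z))
  forward <- r2e > r2o
  uncertain <- p > alpha
  kept <- if (drop_uncertain) forward & !uncertain else forward

  report <- data.frame(
    snp_id = r$snp_id, r2_exp = r2e, r2_out = r2o,
    direction = ifelse(forward, "true", "false"),
    z = z, pval = p, uncertain = uncertain, kept = kept,
    stringsAsFactors = FALSE
  )
  if (any(!kept)) {
    h$dropped <- rbind(h$dropped,
                       data.frame(snp_id = r$snp_id[!kept],
                                  reason = "steiger-direction",
                                  stringsAsFactors = FALSE))
    h$rows <- r[kept, , drop = FALSE]
    rownames(h$rows) <- NULL
  }
  list(harmonized = h, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default instrument-selection configuration
#'
#' @param p_max,maf_min,strict_maf see [filter_significance()].
#' @param r2_max,window_kb see [clump()].
#' @param palindrome_maf_max see [harmonize()].
#' @param outcome_p_max see [exclude_outcome_associated()].
#' @param steiger apply the Steiger directionality filter (default `TRUE`).
#' @param steiger_alpha,steiger_drop_uncertain see [steiger_filter()].
#' @param f_min optional per-SNP F threshold; `NULL` (default) reports F
#'   without excluding any SNP.
#' @return a named list of selection parameters.
#' @export
instrument_config <- function(p_max = 5e-5, maf_min = 0.01,
                              strict_maf = FALSE,
                              r2_max = 0.001, window_kb = 10000,
                              palindrome_maf_max = 0.42,
                              outcome_p_max = 5e-5,
                              steiger = TRUE, steiger_alpha = 0.05,
                              steiger_drop_uncertain = FALSE,
                              f_min = NULL) {
  as.list(environment())
}

#' Build an instrument set through the full selection cascade
#'
#' Applies, in order: the exposure significance/MAF filter, greedy LD
#' clumping, allele harmonization with the palindrome rule,
#' outcome-association exclusion, and Steiger directionality filtering; then
#' computes per-SNP and mean F statistics. Every removal is recorded in a
#' provenance trail.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param panel an [ld_panel].
#' @param config an [instrument_config()] list.
#' @return an object of class `instrument_set`: list with `harmonized`
#'   (the surviving rows), `per_snp_f`, `mean_f`, `weak_flag`,
#'   `steiger_report`, and `provenance` (data frame of filter names and
#'   removal counts). An empty selection raises a condition of class
#'   `netmr_empty_selection` carrying the provenance trail.
#' @export
build_instrument_set <- function(exposure, outcome, panel,
                                 config = instrument_config()) {
  prov <- list()
  note <- function(filter, removed) {
    prov[[length(prov) + 1]] <<- data.frame(filter = filter,
                                            removed = removed,
                                            stringsAsFactors = FALSE)
  }
  fail <- function(msg) {
    stop(empty_selection_condition(msg, provenance = do.call(rbind, prov)))
  }

  n0 <- nrow(exposure$records)
  sig <- tryCatch(
    filter_significance(exposure, p_max = config$p_max,
                        maf_min = config$maf_min,
                        strict_maf = config$strict_maf),
    netmr_empty_selection = function(e) fail(conditionMessage(e)))
  note("significance/MAF", n0 - nrow(sig$records))

  cl <- tryCatch(clump(sig, panel, r2_max = config$r2_max,
                       window_kb = config$window_kb),
                 netmr_empty_selection = function(e) fail(conditionMessage(e)))
  rep_cl <- attr(cl, "clump_report")
  note("clumping", rep_cl$n_absent + rep_cl$n_pruned)

  h <- tryCatch(
    harmonize(cl, outcome, palindrome_maf_max = config$palindrome_maf_max),
    error = function(e) fail(conditionMessage(e)))
  note("harmonization", nrow(cl$records) - nrow(h$rows))
  if (nrow(h$rows) == 0) fail("no SNPs survived harmonization")

  n_before <- nrow(h$rows)
  h <- exclude_outcome_associated(h, p_max = config$outcome_p_max)
  note("outcome-associated", n_before - nrow(h$rows))
  if (nrow(h$rows) == 0) fail("all SNPs outcome-associated")

  steiger_report <- NULL
  if (isTRUE(config$steiger)) {
    n_before <- nrow(h$rows)
    st <- steiger_filter(h, n_exp = exposure$sample_size,
                         n_out = outcome$sample_size,
                         alpha = config$steiger_alpha,
                         drop_uncertain = config$steiger_drop_uncertain)
    h <- st$harmonized
    steiger_report <- st$report
    note("steiger", n_before - nrow(h$rows))
    if (nrow(h$rows) == 0) fail("no SNPs survived Steiger filtering")
  }

  fstat <- compute_f_statistics(h$rows)
  if (!is.null(config$f_min)) {
    weak <- fstat$per_snp_f < config$f_min
    if (any(weak)) {
      h$dropped <- rbind(h$dropped,
                         data.frame(snp_id = h$rows$snp_id[weak],
                                    reason = sprintf("F < %g", config$f_min),
                                    stringsAsFactors = FALSE))
      h$rows <- h$rows[!weak, , drop = FALSE]
      note("weak-instrument F", sum(weak))
      if (nrow(h$rows) == 0) fail("no SNPs with F above f_min")
      fstat <- compute_f_statistics(h$rows)
    } else {
      note("weak-instrument F", 0L)
    }
  }

  structure(
    list(harmonized = h,
         per_snp_f = fstat$per_snp_f,
         mean_f = fstat$mean_f,
         weak_flag = fstat$weak_flag,
         steiger_report = steiger_report,
         provenance = do.call(rbind, prov)),
    class = "instrument_set"
  )
}

#' @rdname build_instrument_set
#' @param x an `instrument_set`.
#' @param ... unused.
#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %d SNPs ('%s' -> '%s'), mean F = %.1f%s\n",
              nrow(x$harmonized$rows), x$harmonized$exposure_id,
              x$harmonized$outcome_id, x$mean_f,
              if (x$weak_flag) " [weak]" else ""))
  print(x$provenance)
  invisible(x)
}
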