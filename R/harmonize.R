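#' Harmonize two traits' summary statistics onto shared effect alleles
#'
#' Aligns the outcome's (or mediator's) per-SNP effects to the exposure's
#' effect allele for every SNP present in both traits, then orients each row
#' so the exposure effect is non-negative ("harmonized on alleles positively
#' associated with the exposure"). Alignment rules, per shared SNP:
#'
#' * matching alleles are kept as-is;
#' * alleles matching after swapping effect/other have the outcome beta
#'   negated and `eaf_out` replaced by `1 - eaf_out`;
#' * alleles matching only after strand complement (or complement plus swap)
#'   are complemented (and the swap rule applied);
#' * palindromic SNPs (A/T or C/G pairs) are dropped when
#'   `min(eaf, 1 - eaf) > palindrome_maf_max` in either trait, dropped when
#'   either trait lacks an allele frequency, and otherwise strand-resolved
#'   by requiring the two traits' frequencies to agree on which allele is
#'   minor;
#' * irreconcilable allele pairs are dropped with a reason.
#'
#' Orientation negates both betas and flips allele labels and frequencies,
#' so each SNP's ratio `beta_out / beta_exp` is preserved exactly, and the
#' procedure is idempotent.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param palindrome_maf_max palindromic SNPs with minor-allele frequency
#'   above this value in either trait are ambiguous and excluded
#'   (default 0.42).
#' @param orient orient rows so `beta_exp >= 0` (default `TRUE`). Set to
#'   `FALSE` when a fixed allele reference must be preserved, as in
#'   multivariable MR set construction.
#' @return an object of class `harmonized_set`: list with `exposure_id`,
#'   `outcome_id`, `rows` (aligned per-SNP data frame), and `dropped`
#'   (data frame of `snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_max = 0.42,
                      orient = TRUE) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (length(shared) == 0) {
    stop("no SNPs shared between '", exposure$trait_id, "' and '",
         outcome$trait_id, "'", call. = FALSE)
  }
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  beta_y <- ou$beta; eaf_y <- ou$eaf
  pal <- is_palindromic(ea_x, oa_x)
  drop_reason <- rep(NA_character_, length(shared))

  # -- palindromic SNPs: letters cannot resolve strand ---------------------
  if (any(pal)) {
    same_pair <- (ea_y == ea_x & oa_y == oa_x) | (ea_y == oa_x & oa_y == ea_x)
    bad <- pal & !same_pair
    drop_reason[bad] <- "incompatible alleles"
    miss_eaf <- pal & same_pair & (is.na(ex$eaf) | is.na(ou$eaf))
    drop_reason[miss_eaf] <- "palindrome with missing EAF"
    maf_x <- pmin(ex$eaf, 1 - ex$eaf)
    maf_y <- pmin(ou$eaf, 1 - ou$eaf)
    ambig <- pal & same_pair & !miss_eaf &
      (maf_x > palindrome_maf_max | maf_y > palindrome_maf_max)
    drop_reason[ambig] <- sprintf("palindrome MAF > %g", palindrome_maf_max)

    keep_pal <- pal & is.na(drop_reason)
    # letter alignment first (a swapped palindrome is also a strand rename,
    # the EAF check below resolves the residual ambiguity)
    swap <- keep_pal & ea_y == oa_x
    beta_y[swap] <- -beta_y[swap]
    eaf_y[swap] <- 1 - eaf_y[swap]
    # strand resolution: both traits must agree on which allele is minor
    flip <- keep_pal & ((ex$eaf < 0.5) != (eaf_y < 0.5))
    beta_y[flip] <- -beta_y[flip]
    eaf_y[flip] <- 1 - eaf_y[flip]
  }

  # -- non-palindromic SNPs ------------------------------------------------
  np <- !pal & is.na(drop_reason)
  cea_y <- allele_complement(ea_y); coa_y <- allele_complement(oa_y)
  direct <- np & ea_y == ea_x & oa_y == oa_x
  swap   <- np & !direct & ea_y == oa_x & oa_y == ea_x
  comp   <- np & !direct & !swap & cea_y == ea_x & coa_y == oa_x
  cswap  <- np & !direct & !swap & !comp & cea_y == oa_x & coa_y == ea_x
  bad    <- np & !(direct | swap | comp | cswap)
  drop_reason[bad] <- "incompatible alleles"
  neg <- swap | cswap
  beta_y[neg] <- -beta_y[neg]
  eaf_y[neg] <- 1 - eaf_y[neg]

  keep <- is.na(drop_reason)
  rows <- data.frame(
    snp_id = shared, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_x, other_allele = oa_x, palindromic = pal,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    pval_exp = ex$pval, n_exp = ex$n,
    beta_out = beta_y, se_out = ou$se, eaf_out = eaf_y,
    pval_out = ou$pval, n_out = ou$n,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  if (orient && nrow(rows)) {
    fl <- rows$beta_exp < 0
    if (any(fl)) {
      ea <- rows$effect_allele[fl]
      rows$effect_allele[fl] <- rows$other_allele[fl]
      rows$other_allele[fl] <- ea
      rows$beta_exp[fl] <- -rows$beta_exp[fl]
      rows$beta_out[fl] <- -rows$beta_out[fl]
      rows$eaf_exp[fl] <- 1 - rows$eaf_exp[fl]
      rows$eaf_out[fl] <- 1 - rows$eaf_out[fl]
    }
  }
  rownames(rows) <- NULL

  structure(
    list(exposure_id = exposure$trait_id,
         outcome_id = outcome$trait_id,
         rows = rows,
         dropped = data.frame(snp_id = shared[!keep],
                              reason = drop_reason[!keep],
                              stringsAsFactors = FALSE)),
    class = "harmonized_set"
  )
}

#' @rdname harmonize
#' @param x a `harmonized_set`.
#' @param ... unused.
#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: '%s' vs '%s', %d SNPs retained, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$rows), nrow(x$dropped)))
  invisible(x)
}

# Rebuild a summary_stats object from one side of a harmonized set; used by
# downstream selection steps that re-enter the cascade.
harmonized_side <- function(h, side = c("exposure", "outcome")) {
  side <- match.arg(side)
  p <- if (side == "exposure") "exp" else "out"
  r <- h$rows
  summary_stats(
    data.frame(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
               effect_allele = r$effect_allele, other_allele = r$other_allele,
               eaf = r[[paste0("eaf_", p)]], beta = r[[paste0("beta_", p)]],
               se = r[[paste0("se_", p)]], pval = r[[paste0("pval_", p)]],
               n = r[[paste0("n_", p)]], stringsAsFactors = FALSE),
    trait_id = if (side == "exposure") h$exposure_id else h$outcome_id
  )
}
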