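# Fixtures built in code: small summary-stat tables, harmonized rows, and
# generator shortcuts shared across test files.

make_records <- function(n = 5, seed = 1, beta = NULL, se = 0.02,
                         eaf = NULL, pval = NULL, alleles = c("A", "G")) {
  set.seed(seed)
  if (is.null(beta)) beta <- rnorm(n, 0.1, 0.02)
  if (is.null(eaf)) eaf <- runif(n, 0.1, 0.5)
  se <- rep_len(se, n)
  df <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1e6,
    effect_allele = alleles[1], other_allele = alleles[2],
    eaf = eaf, beta = beta, se = se,
    n = 10000, stringsAsFactors = FALSE
  )
  df$pval <- if (is.null(pval)) 2 * pnorm(-abs(df$beta / df$se)) else pval
  df
}

make_ss <- function(..., trait_id = "trait", sample_size = 10000) {
  summary_stats(make_records(...), trait_id = trait_id,
                sample_size = sample_size)
}

# Harmonized-style rows straight from per-SNP effects, bypassing allele
# bookkeeping; the shape every estimator consumes.
make_rows <- function(bx, by, sx, sy) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_along(bx)),
    beta_exp = bx, se_exp = rep_len(sx, length(bx)),
    beta_out = by, se_out = rep_len(sy, length(bx)),
    stringsAsFactors = FALSE
  )
}

# Random estimator instance with known generative slope.
random_rows <- function(n, beta = 0.2, seed = 1, sx = 0.02, sy = 0.01,
                        gamma_sd = 0.08) {
  set.seed(seed)
  gamma <- rnorm(n, 0, gamma_sd)
  make_rows(bx = rnorm(n, gamma, sx), by = rnorm(n, beta * gamma, sy),
            sx = sx, sy = sy)
}

# Exposure/outcome rows taken directly from a simulated triplet (all
# exposure-role SNPs, no selection cascade) for calibration loops.
sim_instrument_rows <- function(cfg) {
  sim <- simulate_gwas_triplet(cfg)
  harmonize(sim$exposure, sim$outcome)$rows
}

# identity LD panel over a set of SNPs
flat_panel <- function(snp_ids, chrom = "1", pos = NULL) {
  n <- length(snp_ids)
  if (is.null(pos)) pos <- seq_len(n) * 1e6
  ld_panel(snp_ids, diag(n),
           data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE))
}
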