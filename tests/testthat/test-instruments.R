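# Instrument selection: filters, F statistics, clumping, Steiger.

test_that("significance and MAF thresholds are applied as strict bounds", {
  df <- make_records(3, eaf = c(0.3, 0.3, 0.005),
                     pval = c(1e-6, 1e-4, 1e-6))
  ss <- summary_stats(df, "t")
  kept <- filter_significance(ss)
  expect_equal(kept$records$snp_id, "rs001")  # p 1e-4 and maf 0.005 removed

  expect_error(filter_significance(ss, p_max = 1e-10),
               class = "netmr_empty_selection")

  # records lacking EAF pass with a warning unless strict
  df$eaf <- NA
  ss_na <- summary_stats(df, "t")
  expect_warning(kept2 <- filter_significance(ss_na), "lack EAF")
  expect_equal(nrow(kept2$records), 2)
  expect_error(
    suppressWarnings(filter_significance(ss_na, strict_maf = TRUE)),
    class = "netmr_empty_selection")
})

test_that("F statistics and the weak-instrument flag follow (beta/se)^2", {
  ss <- summary_stats(make_records(2, beta = c(0.1, 0.02), se = 0.02), "t")
  f <- compute_f_statistics(ss)
  expect_equal(unname(f$per_snp_f), c(25, 1))
  expect_equal(f$mean_f, 13)
  expect_false(f$weak_flag)
  expect_true(compute_f_statistics(
    summary_stats(make_records(1, beta = 0.02, se = 0.02), "t"))$weak_flag)
})

test_that("greedy clumping keeps the most significant SNP per dependent set", {
  df <- make_records(3, pval = c(1e-8, 1e-6, 1e-5))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  panel <- ld_panel(df$snp_id, r2,
                    data.frame(snp_id = df$snp_id, chrom = "1",
                               pos = c(1e6, 1e6 + 5e4, 5e7)))
  out <- clump(summary_stats(df, "t"), panel)
  expect_setequal(out$records$snp_id, c("rs001", "rs003"))

  # pairwise independence: identity panel keeps everything
  out2 <- clump(summary_stats(df, "t"), flat_panel(df$snp_id))
  expect_equal(nrow(out2$records), 3)

  # equal p: tie broken by (chrom, pos)
  df3 <- make_records(2, pval = c(1e-6, 1e-6))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  panel3 <- ld_panel(df3$snp_id, r2,
                     data.frame(snp_id = df3$snp_id, chrom = "1",
                                pos = c(2e6, 1e6)))
  out3 <- clump(summary_stats(df3, "t"), panel3)
  expect_equal(out3$records$snp_id, "rs002")  # earlier position wins
})

test_that("clumped output never contains a dependent pair (brute force)", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 60
    ids <- sprintf("s%02d", 1:n)
    # random block structure
    blocks <- sort(sample(1:12, n, replace = TRUE))
    r2 <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0))
    diag(r2) <- 1
    pos <- cumsum(sample(c(1e3, 1e7), n, replace = TRUE))
    panel <- ld_panel(ids, r2, data.frame(snp_id = ids, chrom = "1",
                                          pos = pos))
    df <- make_records(n)
    df$snp_id <- ids
    df$pval <- runif(n)
    out <- clump(summary_stats(df, "t"), panel, r2_max = 0.1,
                 window_kb = 10000)
    kept <- match(out$records$snp_id, ids)
    for (i in kept) for (j in kept) {
      if (i < j) {
        expect_false(r2[i, j] > 0.1 && abs(pos[i] - pos[j]) <= 1e7)
      }
    }
    # provenance conservation
    rep_cl <- attr(out, "clump_report")
    expect_equal(nrow(out$records) + rep_cl$n_pruned + rep_cl$n_absent, n)
  }
})

test_that("outcome-associated SNPs are excluded with a recorded reason", {
  rows <- make_rows(bx = c(0.1, 0.1), by = c(0.05, 0.01), sx = 0.02,
                    sy = 0.01)
  h <- structure(list(exposure_id = "e", outcome_id = "o",
                      rows = cbind(rows, pval_out = c(1e-6, 0.3)),
                      dropped = data.frame(snp_id = character(0),
                                           reason = character(0))),
                 class = "harmonized_set")
  out <- exclude_outcome_associated(h)
  expect_equal(out$rows$snp_id, "rs002")
  expect_equal(out$dropped$reason, "outcome-associated")
})

test_that("Steiger filtering keeps SNPs explaining more exposure variance", {
  mk <- function(p_exp, p_out, n_exp = 10000, n_out = 10000) {
    rows <- make_rows(bx = 0.1, by = 0.02, sx = 0.02, sy = 0.02)
    rows$pval_exp <- p_exp; rows$pval_out <- p_out
    rows$n_exp <- n_exp; rows$n_out <- n_out
    structure(list(exposure_id = "e", outcome_id = "o", rows = rows,
                   dropped = data.frame(snp_id = character(0),
                                        reason = character(0))),
              class = "harmonized_set")
  }
  st <- steiger_filter(mk(1e-8, 1e-3))
  expect_equal(st$report$direction, "true")
  expect_equal(nrow(st$harmonized$rows), 1)

  # equal variance explained: not strictly greater, dropped
  st2 <- steiger_filter(mk(1e-4, 1e-4))
  expect_equal(nrow(st2$harmonized$rows), 0)

  # frozen oracle: p_exp 1e-20 / p_out 0.5 at the study's sample sizes
  st3 <- steiger_filter(mk(1e-20, 0.5, 14306, 462341))
  expect_equal(st3$report$r2_exp, 6.075205e-3, tolerance = 1e-6)
  expect_equal(st3$report$r2_out, 9.839879e-7, tolerance = 1e-6)
  expect_equal(st3$report$z, 9.082569, tolerance = 1e-6)
  expect_lt(st3$report$pval, 0.05)
  expect_true(st3$report$kept)

  # swapping trait labels reverses the decision symmetrically
  st4 <- steiger_filter(mk(1e-3, 1e-8))
  expect_equal(st4$report$direction, "false")
  expect_equal(st4$report$z, -st$report$z, tolerance = 1e-10)

  expect_error(steiger_filter(mk(1e-8, 1e-3, n_exp = 2)), "above 3")
})

test_that("the full cascade yields a provenance-conserving instrument set", {
  sim <- simulate_gwas_triplet(sim_config(n_snps = 50, n_snps_med = 0,
                                          n_snps_out = 0, mean_f = 80,
                                          beta_EM = 0, beta_MO = 0,
                                          beta_EO_direct = 0, seed = 21))
  iset <- build_instrument_set(sim$exposure, sim$outcome, sim$panel)
  expect_s3_class(iset, "instrument_set")
  # null outcome: most strong instruments survive
  expect_gt(nrow(iset$harmonized$rows), 25)
  expect_gt(iset$mean_f, 10)
  expect_false(iset$weak_flag)
  # provenance conservation across the cascade
  expect_equal(nrow(sim$exposure$records) - sum(iset$provenance$removed),
               nrow(iset$harmonized$rows))

  # one LD block: exactly one survivor
  sim2 <- simulate_gwas_triplet(sim_config(n_snps = 12, n_snps_med = 0,
                                           n_snps_out = 0, mean_f = 200,
                                           ld_block_size = 12,
                                           ld_within_r2 = 0.9,
                                           beta_EM = 0, beta_MO = 0,
                                           beta_EO_direct = 0, seed = 22))
  iset2 <- build_instrument_set(sim2$exposure, sim2$outcome, sim2$panel)
  expect_equal(nrow(iset2$harmonized$rows), 1)
})

test_that("a reverse-causal structure is caught by the Steiger filter", {
  # outcome drives the exposure; equal sample sizes so selection still finds
  # the leaked signals, which Steiger must then reject
  cfg <- sim_config(n_snps = 5, n_snps_med = 0, n_snps_out = 60,
                    n_exp = 20000, n_out = 20000, mean_f = 150,
                    beta_EM = 0, beta_MO = 0, beta_EO_direct = 0,
                    reverse_effect = 0.8, seed = 33)
  sim <- simulate_gwas_triplet(cfg)
  cfg_sel <- instrument_config(steiger = FALSE, outcome_p_max = 0)
  # outcome_p_max 0 disables the outcome-association exclusion so the
  # Steiger step is isolated
  pre <- build_instrument_set(sim$exposure, sim$outcome, sim$panel, cfg_sel)
  reverse_snps <- sim$truth$snp_id[sim$truth$role == "out"]
  leaked <- sum(pre$harmonized$rows$snp_id %in% reverse_snps)
  expect_gt(leaked, 10)  # reverse path leaks into exposure selection
  st <- steiger_filter(pre$harmonized)
  rejected <- st$report$snp_id[!st$report$kept]
  expect_gt(length(intersect(rejected, reverse_snps)) / leaked, 0.5)
})
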