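# netmr — network Mendelian randomization from GWAS summary statistics

`netmr` is an R package for **two-sample Mendelian randomization (MR)**:
estimating the causal effect of an exposure on an outcome from GWAS summary
statistics, using genetic variants as instrumental variables. It was built
for microbiome-to-disease screening studies — many small-GWAS exposures
(gut-microbiota abundances), large binary-trait outcomes (sleep disorders),
and a **network (two-step) MR** extension that quantifies how much of an
exposure's effect flows through a candidate mediator (pain, obesity,
smoking, microbial metabolic pathways, ...).

For SNP *j* with exposure association γ̂ⱼ (SE σ_γⱼ) and outcome association
Γ̂ⱼ (SE σ_Γⱼ) from non-overlapping samples, a valid instrument satisfies
Γⱼ = β·γⱼ. The primary estimator is inverse-variance weighting over the
per-SNP Wald ratios,

    β̂_IVW = Σⱼ γ̂ⱼ Γ̂ⱼ / σ²_Γⱼ  ÷  Σⱼ γ̂ⱼ² / σ²_Γⱼ ,

with Cochran's Q heterogeneity and multiplicative random-effects inflation.
Around it the package provides the full screening apparatus:

* **I/O + harmonization** — delimited summary-statistic tables with
  configurable columns; allele alignment with strand complements and the
  palindrome MAF > 0.42 exclusion (`read_summary_stats()`, `harmonize()`).
* **Instrument selection** — p < 5e-5 and MAF ≥ 0.01 filters, greedy LD
  clumping (r² > 0.001 within 10,000 kb) against a text LD panel,
  outcome-association exclusion, Steiger directionality filtering, and
  per-SNP F statistics with full provenance (`build_instrument_set()`).
* **Nine estimators** — IVW, maximum likelihood, weighted median, MR-Egger,
  MR-PRESSO, dIVW, contamination mixture (ConMix), MR-RAPS, cML-MA
  (`mr_ivw()`, `mr_ml()`, `mr_weighted_median()`, `mr_egger()`,
  `mr_presso()`, `mr_divw()`, `mr_conmix()`, `mr_raps()`, `mr_cml_ma()`,
  or all at once via `mr_run()`).
* **Sensitivity battery + evidence tiers** — Cochran's Q, Egger intercept,
  PRESSO global/outlier tests, leave-one-out, reverse MR, and the
  "probable causality" / "causality" classifier with Bonferroni threshold
  0.05/(exposures screened) (`run_sensitivity_suite()`,
  `classify_evidence()`).
* **Multivariable MR** — joint instrument construction and weighted
  multivariable IVW/Egger for conditional effects (`build_mvmr_set()`,
  `mvmr_ivw()`, `mvmr_egger()`).
* **Two-step mediation** — β1 (exposure→mediator), β2 (mediator→outcome
  adjusted for the exposure), indirect effect β1·β2 with delta-method SE,
  mediation proportion with CI, and the three-criterion mediator screen
  (`run_network_mr()`, `mediation_effect()`, `mediation_proportion()`).
* **Synthetic GWAS generator** — two-sample summary statistics under a
  known exposure→mediator→outcome graph with configurable instrument
  strength, pleiotropy, LD blocks and reverse causation, so the whole
  pipeline is testable offline (`simulate_gwas_triplet()`, `sim_config()`).
* **Panel-scale drivers** — `run_uvmr_screen()` and `run_full_study()`
  produce report tables shaped like published screening tables, with
  per-pair fault isolation and a filter-count audit log. A thin CLI over
  these functions ships in `inst/cli/mr.R`.

## Worked example

```r
library(netmr)

sim  <- simulate_gwas_triplet(sim_config(seed = 7))   # truth: total 0.2, 25% mediated
iset <- build_instrument_set(sim$exposure, sim$outcome, sim$panel)
iset
#> instrument_set: 46 SNPs ('exposure' -> 'outcome'), mean F = 52.7
#>               filter removed
#> 1   significance/MAF     153
#> 2           clumping       0
#> 3      harmonization       0
#> 4 outcome-associated       1
#> 5            steiger       0

mr_table(mr_run(iset, methods = c("ivw", "ml", "wm", "egger"),
                seed = 1, wm_n_boot = 200))
#>     method n_snp      beta         se     ci_low   ci_high         pval
#> 1      IVW    46 0.1532998 0.01718260 0.11962256 0.1869771 4.587451e-19
#> 2       ML    46 0.1556816 0.01760648 0.12117352 0.1901896 9.377609e-19
#> 3       WM    46 0.1442261 0.02715675 0.09099987 0.1974524 1.091001e-07
#> 4 MR-Egger    46 0.2203000 0.06214660 0.09849490 0.3421051 3.928456e-04
```

Of the 200 simulated SNPs, 46 survive the selection cascade (153 fail the
p < 5e-5 exposure filter — most SNPs in this simulation instrument the
mediator or outcome, not the exposure — and one is excluded as
outcome-associated). All four estimators agree on a positive causal effect;
the IVW estimate 0.153 is the *total* effect of this exposure as seen
through its instruments.

The two-step mediation analysis decomposes it:

```r
run_network_mr(sim$exposure, sim$mediator, sim$outcome, sim$panel,
               seed = 1, presso_n_sim = 300, wm_n_boot = 300)
#> mediation_result: exposure -> mediator -> outcome
#>   total  = 0.1533 (p = 4.59e-19), tier: causality
#>   beta1  = 0.4789 (p = 2.76e-70), beta2 = 0.08615 (p = 1.29e-07)
#>   indirect = 0.04126 (95% CI 0.02528, 0.05724)
#>   proportion mediated = 26.9% (95% CI 14.9%, 38.9%)
```

β1 is the exposure's effect on the mediator, β2 the mediator's effect on
the outcome holding the exposure fixed (multivariable MR); their product is
the mediated (indirect) effect, and dividing by the total effect gives the
proportion mediated — here 26.9% (95% CI 14.9–38.9%), covering this
simulation's generative truth of 25%. The "causality" tier means the IVW
p-value passed the Bonferroni bound, at least three of the four secondary
estimators agreed, and no sensitivity flag (heterogeneity, pleiotropy,
outliers, reverse causation) was raised.

See `vignettes/network-mr-methods.Rmd` for the models, assumptions, and
design decisions.

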