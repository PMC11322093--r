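---
title: "Network Mendelian randomization with netmr: models, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Mendelian randomization with netmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone, using genetic
variants as instrumental variables. For SNP $j$, write $\hat\gamma_j$
(standard error $\sigma_{\gamma j}$) for its association with the exposure
and $\hat\Gamma_j$ ($\sigma_{\Gamma j}$) for its association with the
outcome, estimated in non-overlapping samples. If SNP $j$ is a valid
instrument — associated with the exposure, affecting the outcome only
through the exposure, and independent of confounders — then
$\Gamma_j = \beta\,\gamma_j$ and the Wald ratio
$\hat\Gamma_j/\hat\gamma_j$ estimates the causal effect $\beta$.

netmr implements this machinery for the setting that motivated it: a panel
of gut-microbiota abundance exposures (small GWAS, few genome-wide-significant
variants), disease outcomes such as sleep disorders (large biobank GWAS,
log-odds scale), and a *network* (two-step) extension that decomposes the
exposure–outcome effect through candidate mediators such as pain, obesity,
smoking, or microbial metabolic-pathway abundances.

## Instrument selection

`build_instrument_set()` applies, in order:

1. **Significance and frequency filter** — `pval < 5e-5` and MAF $\ge$ 0.01.
   The relaxed threshold (rather than 5e-8) reflects the scarcity of
   genome-wide-significant microbial-abundance associations; it buys
   instruments at the price of weak-instrument bias, which is why the F
   statistics and the dIVW/RAPS estimators are reported alongside.
2. **Greedy LD clumping** — repeatedly keep the smallest-p SNP and discard
   SNPs with $r^2 > 0.001$ within 10,000 kb of it, against a user-supplied
   LD panel (`ld_panel()`). Clumping is implemented internally rather than
   delegated to external tooling so a synthetic panel makes the whole
   cascade testable offline. Ties on p-value break by (chrom, pos, id).
3. **Harmonization** — both traits aligned to the allele positively
   associated with the exposure. Palindromic (A/T, C/G) SNPs are dropped
   when MAF > 0.42 in either trait; retained palindromes are
   strand-resolved by requiring the two traits' frequencies to agree on the
   minor allele, and dropped if either frequency is missing (the
   conservative choice; letters alone cannot resolve them).
4. **Outcome-association exclusion** — SNPs with outcome `pval < 5e-5` are
   removed as potential reverse-causation carriers.
5. **Steiger filtering** — a SNP is kept only if it explains more variance
   in the exposure than in the outcome, with $r^2$ derived from (p, n) via
   $r^2 = F/(F + n - 2)$. This route needs no phenotype-variance model, so
   binary outcomes are handled identically. The direction z-test
   (Fisher-transformed correlations, two independent samples) marks
   "uncertain" SNPs; they are kept when the point inequality favours the
   exposure, with a conservative drop mode available
   (`steiger_drop_uncertain`).

Per-SNP F statistics $(\hat\gamma/\sigma_\gamma)^2$ and their mean are
always reported; mean F $\le 10$ raises a weak-instrument flag. By default
no SNP is excluded on F alone (`f_min = NULL`) — the filter cascade already
conditions heavily on the exposure association, and a hard F cut would
merely re-apply the same selection.

Every removal is recorded in a provenance table; counts are conserved
exactly (input = retained + removed), which the tests verify.

## The estimator suite

All estimators consume the same harmonized rows.

* **IVW** (primary): weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin, weights $1/\sigma_\Gamma^2$. Fixed-effects SE
  $(\sum\hat\gamma^2/\sigma_\Gamma^2)^{-1/2}$; under multiplicative random
  effects the SE is inflated by $\max(1, \sqrt{Q/(n-1)})$ where $Q$ is
  Cochran's statistic. The default `"auto"` applies random effects when
  $Q/(n-1) > 1$, the convention of the standard two-sample MR workflow.
* **Maximum likelihood**: joint normal likelihood over
  $(\beta, \gamma_1..\gamma_n)$, profiled over the $\gamma_j$ in closed
  form and optimized in one dimension; SE from the observed information of
  the full parameter block (block inversion).
* **Weighted median**: weighted 50th percentile of the Wald ratios with
  cumulative-weight interpolation $p_j = (S_j - w_j/2)/S_n$; consistent
  while valid instruments hold >50% of the weight. SE by parametric
  bootstrap (default 1000 resamples, seedable) — the convention for this
  estimator, which has no convenient closed-form variance.
* **MR-Egger**: weighted regression *with* intercept on rows oriented
  $\hat\gamma \ge 0$; the slope is consistent under InSIDE even with
  directional pleiotropy, and the intercept is the pleiotropy test.
* **MR-PRESSO**: leave-one-out expected outcome effects give a weighted
  residual sum of squares whose null distribution is built from parametric
  simulation (default 1000 draws); per-SNP outlier p-values are
  Bonferroni-corrected; the corrected estimate is IVW without flagged
  outliers, with a permutation distortion test.
* **dIVW**: subtracts $\sigma_\gamma^2$ from the squared exposure effects
  in IVW's denominator, removing weak-instrument attenuation; sandwich SE.
* **ConMix**: profile likelihood over a 2001-point grid spanning the ratio
  range $\pm 3\times$ the largest ratio SE; each SNP contributes the larger
  of a valid component $N(\beta, se_j^2)$ and an invalid component
  $N(0, se_j^2 + \psi^2)$ with $\psi = 1.5\,\mathrm{sd}(\text{ratios})$.
  The 95% CI is the grid region within $\chi^2_1(0.95)/2$ of the maximum;
  a disjoint region triggers a warning and its range is reported.
* **MR-RAPS**: robustified profile score with standardized residuals
  $t_j = (\hat\Gamma_j - \beta\hat\gamma_j) / \sqrt{\sigma_{\Gamma j}^2 +
  \beta^2\sigma_{\gamma j}^2 + \tau^2}$ and an overdispersion parameter
  $\tau^2$ fitted jointly (Huber loss by default). The score is the exact
  gradient of the bounded robust loss $\sum_j \rho(t_j)$ and vanishes at
  $\beta \to \pm\infty$, so the estimate is found by minimizing the loss on
  an interval around the IVW start (expanded while the optimum touches the
  boundary) rather than by root-hunting; sandwich SE.
* **cML-MA**: for each candidate invalid count $K$, constrained ML gives
  exactly $K$ SNPs a free pleiotropy offset (iteratively re-selected by
  likelihood gain); per-$K$ estimates are combined with BIC weights. The
  BIC penalty is $K \log n$ with $n$ the GWAS sample size (the method's
  convention) — with $\log(\text{SNP count})$ the expected maximum residual
  ($\approx 2\log n_{snp}$) always beats the penalty and $K=0$ could never
  win on clean data. The default is the deterministic no-perturbation
  variant; data perturbation is opt-in.

All two-sided p-values use the normal approximation on $\hat\beta/SE$,
matching the reporting granularity of published screening tables.

## Sensitivity battery and evidence tiers

`run_sensitivity_suite()` aggregates Cochran's Q, the Egger intercept,
MR-PRESSO global/outlier/distortion tests, leave-one-out IVW (with a
single-SNP-driver flag), the Steiger retention summary, and reverse MR
(roles swapped, full cascade rerun). Flags are pure functions of the stored
statistics at a configurable $\alpha$ (default 0.05):

* heterogeneity: Q-test significant;
* pleiotropy: Egger intercept *or* PRESSO global test significant;
* outliers: PRESSO flagged SNPs *and* the corrected estimate disagrees with
  the raw one in sign or significance ("affected by outliers" is not
  defined in the screening convention this implements; this
  operationalization is a documented choice);
* reverse causation: reverse IVW significant *or* Steiger retained fewer
  than half the instruments.

`classify_evidence()` then assigns tiers: *probable causality* requires IVW
p < 0.05, at least three of the four secondary methods (ML, weighted
median, Egger, PRESSO) significant with the same sign ("support" is taken
to require same-sign significance), and all flags off; *causality*
additionally requires IVW p below the Bonferroni bound 0.05/(number of
exposures screened), 0.05/196 for the full named-microbiota panel.

## Multivariable MR and the two-step mediation analysis

`build_mvmr_set()` takes the union of each exposure's filtered, clumped
instruments, re-clumps jointly (smallest per-SNP p across exposures wins),
restricts to SNPs measured in every trait, and aligns all effects to the
outcome's allele reference without orientation flipping (a fixed reference
is what keeps the columns commensurable). An intersection mode is
available. `mvmr_ivw()` is the weighted multivariable regression without
intercept; `mvmr_egger()` adds an intercept on rows oriented to a chosen
exposure. Conditional F statistics are reported per exposure as a
weak-instrument diagnostic.

The network decomposition estimates, for exposure E, mediator M, outcome Y:
$\beta_1$ (E→M, univariable), $\beta_2$ (M→Y adjusted for E, multivariable),
the total effect (E→Y, univariable), the indirect effect
$\beta_1\beta_2$ with first-order delta SE
$\sqrt{\beta_2^2\sigma_1^2 + \beta_1^2\sigma_2^2}$, and the mediation
proportion indirect/total with a delta-method CI
($\mathrm{Var} \approx \mathrm{Var}(IE)/TE^2 + IE^2\,\mathrm{Var}(TE)/TE^4$).
The proportion CI treats indirect and total as independent although the
two-step estimates share instruments; their correlation is positive, so the
independence approximation widens the interval (conservative). A
Monte-Carlo percentile interval is available (`method = "mc"`).

A mediator is screened in only if (1) E→M is significant, (2) M→Y remains
significant after adjusting for E, and (3) the sign of $\beta_1\beta_2$
matches the sign of the total effect.

One deliberate deviation inside `run_network_mr()`: the outcome-association
exclusion (step 4 of the cascade) is **not** applied on the E→M leg. That
rule guards exposure→outcome analyses against reverse causation; applied
against the mediator it removes instruments *because* they are associated
with the trait whose effect $\beta_1$ estimates, which deletes the signal
the mediator criteria require and measurably attenuates $\beta_1$. Steiger
filtering still applies on that leg.

## The synthetic generator

`simulate_gwas_triplet()` draws three non-overlapping GWAS samples under a
linear causal graph E→M→Y with direct E→Y and optional reverse Y→E paths.
SNPs come in three blocks: exposure instruments ($\gamma \sim N(0, s^2)$
with $s$ calibrated so the expected mean per-SNP F equals `mean_f`),
mediator-specific instruments, and outcome-specific instruments. The
mediator-specific block is load-bearing: without SNPs that move the
mediator independently of the exposure, the multivariable design matrix is
collinear by construction and the conditional mediator effect is
unidentified; the outcome-specific block is what gives reverse MR something
to select. Sampling noise uses the standardized-trait approximation
$\sigma^2 = 1/(2\,\mathrm{MAF}(1-\mathrm{MAF})\,n)$, independent across
the three samples. Pleiotropy assigns a fraction of exposure instruments
direct outcome effects $\alpha \sim N(\mu_\alpha, \sigma_\alpha)$
(balanced when $\mu_\alpha = 0$); an InSIDE-violation option adds
$0.3\gamma_j$ to $\alpha_j$. LD blocks give exposure instruments an
exchangeable true-effect correlation $\sqrt{r^2}$ and a matching
block-diagonal $r^2$ panel.

Default conditions: exposure GWAS n = 14,306 (the scale of the largest
published 16S microbial-QTL meta-analysis), mediator GWAS n = 7,700 (the
scale of published gut metabolic-pathway GWAS), outcome GWAS n = 20,000
read as an effective sample size for ascertained binary sleep phenotypes;
MAF uniform on (0.05, 0.5); target mean F 30; effects
$\beta_{EM} = 0.5$, $\beta_{MO} = 0.1$, direct 0.15, hence total 0.2 and
true mediation proportion 25%; no pleiotropy; no LD; no palindromes. The
downstream sample sizes are deliberately *not* biobank-scale: with the
default effect sizes and n in the hundreds of thousands, essentially every
valid instrument becomes "outcome-associated" at 5e-5 and the cascade's
own exclusion step degenerates — the generator emulates the operating
regime of the real screening study, where instruments' downstream
z-scores sit below that threshold.

What the generator does *not* emulate: real microbiome abundance
distributions (zero inflation, compositionality), binary-trait likelihoods
(log-odds effects are approximated by the same normal noise model), LD
between estimated — as opposed to true — effects, sample overlap, and
population stratification. Passing tests therefore validate the
statistical machinery under its stated assumptions, not robustness to
these real-data features.

## Validation studies and their problem sizes

The packaged studies (`study_*`, also run by `scripts/acceptance.R`) use:

* oracle agreement: 100 random instances, IVW/MVMR vs `lm()` WLS fits,
  agreement to 1e-10;
* type-I error: 1000 null replicates, 30 instruments each, IVW/ML/weighted
  median/Egger at $\alpha = 0.05$, judged against the exact binomial 99%
  interval around 0.05. The weighted median sits at the conservative edge
  of that interval (rejection ≈ 0.034): its parametric-bootstrap SE
  resamples around the already-noisy summary statistics and overestimates
  the sampling SD by roughly 8% at mean F 30 — a property of the
  published SE procedure itself, visible in the original method's
  simulations as well;
* coverage: 500 replicates, 100 strong instruments (mean F 100), true
  effect 0.1, IVW/ML/dIVW/RAPS 95% CIs expected to cover at 93–97%;
* outlier robustness: 100 datasets of 25 instruments with one 10-SE spike,
  MR-PRESSO detection and corrected-estimate accuracy;
* mediation recovery: 500 replicates of the full two-step pipeline on the
  default mediated graph with mean F 100, coverage of the 25% proportion
  and delta-vs-Monte-Carlo SE agreement.

The mediation study uses the strong-instrument regime deliberately: at
mean F around 30, the p < 5e-5 selection truncates the instrument
distribution and the selected $\hat\gamma$ are inflated (winner's curse),
attenuating every ratio estimate by roughly 10% — an artifact of
selecting and estimating on the same exposure data. The attenuation
largely cancels in the mediation *proportion* (numerator and denominator
share the exposure instruments), but it is a known limitation of the
screening design itself, affecting real analyses of this type, and is the
reason the recovery study isolates the mediation calculus from it.

## Numerical choices and degenerate inputs

* Exact fits (zero residual) are handled explicitly: Egger SEs come from
  the weighted design matrix, not the residual scale.
* ML and cML optimize a profiled 1-d likelihood (tolerance 1e-10) with the
  search interval spanning the ratio range around the IVW start; the cML SE
  comes from the valid-set information matrix, and non-converged K values
  are dropped with a warning (all-K failure is an error).
* MR-PRESSO's global p is the plain fraction of simulated RSS at or above
  the observed one; with 1000 simulations the smallest reportable p is 0.
* Empty selections raise a typed condition (`netmr_empty_selection`)
  carrying the provenance trail; pipeline drivers convert it into a
  "not evaluable" row rather than failing the run.
* Duplicate SNP ids keep the smallest-p record; indels and multi-allelic
  records are rejected at load (the instruments of interest are biallelic
  SNPs); missing p-values are back-filled from beta/se by the two-sided
  normal.
* Missing EAF: non-palindromic SNPs harmonize by letters alone and pass
  the MAF filter with a warning (strict mode available); palindromic SNPs
  without EAF are dropped.

## Worked example

```{r example}
sim <- simulate_gwas_triplet(sim_config(seed = 7))
iset <- build_instrument_set(sim$exposure, sim$outcome, sim$panel)
iset
mr_table(mr_run(iset, methods = c("ivw", "ml", "wm", "egger"),
                seed = 1, wm_n_boot = 200))
res <- run_network_mr(sim$exposure, sim$mediator, sim$outcome, sim$panel,
                      seed = 1, presso_n_sim = 300, wm_n_boot = 300)
res
```

The generative truth here is a total effect of 0.2 with 25% mediated; the
printed proportion interval should (and does, for this seed) cover it.
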