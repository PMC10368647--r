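---
title: "Correcting attenuation bias in polygenic index regressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting attenuation bias in polygenic index regressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A polygenic index (PGI) is a weighted sum of allele counts across SNPs, with
weights taken from GWAS coefficients. Because the GWAS discovery sample is
finite, the estimated weights are noisy, and the resulting PGI is a noisy
proxy of the latent additive SNP factor PGI\* — the best linear predictor of
the phenotype from the measured variants. Regressing an outcome $Y$
(standardized) on a standardized PGI therefore suffers classical
measurement-error attenuation: with $\mathrm{PGI} = \mathrm{PGI}^* + \nu$,

$$\hat\beta_{st} = \beta_{st}
  \frac{\sigma_{PGI^*}}{\sqrt{\sigma^2_{PGI^*} + \sigma^2_\nu}} < \beta_{st},
  \qquad
  \frac{\hat\beta_{st}^2}{\beta_{st}^2} = \frac{R^2}{h^2_{SNP}},$$

so the attenuation is governed by the ratio of the PGI's $R^2$ to the SNP
heritability, the upper bound of PGI predictive power. Under the equal-
contribution assumption the expected $R^2$ has a closed form, implemented in
`expected_r2()`:

$$R^2 \approx h^2_{SNP}\,\frac{h^2_{SNP}}{h^2_{SNP} + M/N_{GWAS}}.$$

This package implements and compares, on fully simulated family data, three
estimators of the standardized effect of the *true* latent PGI:

* **meta-OLS** (`ols_pgi()`): OLS on a PGI built from the inverse-variance
  meta-analysis of two GWAS — the common practice, and the attenuated
  benchmark;
* **ORIV** (`oriv()`): obviously-related instrumental variables. Two PGIs
  built from non-overlapping GWAS are each divided by the square root of
  their sample correlation and used as mutual instruments in a stacked 2SLS
  with stack-specific intercepts, standard errors clustered on the
  individual (the data enter twice). The scaling makes the estimand the
  standardized effect of the true PGI directly;
* **PGI-RC** (`pgi_rc()`): the repository correction, which multiplies the
  OLS coefficient by $\sqrt{h^2_{SNP}/R^2}$ using a GREML estimate of
  $h^2_{SNP}$ in the analysis sample. In the univariate case the corrected
  point estimate is exactly $\sqrt{\hat h^2_{SNP}}$ — the function asserts
  this identity. Two standard errors are reported: the default, which treats
  the scaling factor as fixed (scales the OLS SE by the same factor), and a
  Delta-method variant $se(\hat h^2)/(2\sqrt{\hat h^2})$ that carries the
  GREML uncertainty.

## The simulator

`simulate_study()` is a forward-in-time simulator of unlinked diploid
genotypes. Three samples are generated — two GWAS discovery samples and one
prediction sample of complete sibling pairs — as separate sub-populations
sharing a founder allele-frequency spectrum drawn uniformly from
`founder_maf_range` (default $U(0.1, 0.5)$; the interval is configurable
because founder frequencies are a free parameter of the design). Each
generation:

1. **Mating** (`mate()`): the generation is split at random into two pools;
   pool A is sorted by phenotype and pool B by the Gaussian-coupled index
   $\rho Y + \sqrt{1-\rho^2}\,z$, and mates are paired by rank. Because the
   index has the same marginal as the phenotype, the realized mate
   correlation converges to the target $\rho$ without iterative tuning, and
   $\rho = 0$ / $\rho = 1$ reduce to random and perfect sorting.
2. **Reproduction** (`reproduce()`): every couple has exactly two children;
   each child receives per SNP one allele from each parent, drawn uniformly
   from that parent's two (no linkage, no mutation, no selection).
3. **Phenotype** (`assign_phenotype()`):
   $Y = \sqrt{h^2}\,G_{st} + \sqrt{n^2}\,P_{st} + e$, where $G_{st}$ is the
   direct genetic factor (genotypes weighted by the direct effects,
   standardized within the generation) and $P_{st}$ is the genetic-nurture
   factor (the *parental* genotypes weighted by an independent nurture
   effect vector, standardized). The environmental variance is
   $1 - h^2 - n^2$.

Because a child's genotype carries half the parental genotype signal, the
SNP heritability visible to GREML is $h^2_{SNP} = h^2 + n^2/2$; the default
genetic-nurture parametrization ($h^2 = 0.2$, $n^2 = 0.1$) keeps
$h^2_{SNP} = 0.25$, equal to the no-nurture baseline ($h^2 = 0.25$,
$n^2 = 0$).

Design choices worth calling out:

* **Per-generation standardization** of the latent factors (default on)
  keeps the contemporary heritability — and hence the target coefficient —
  fixed under assortative mating, which otherwise inflates genetic variance
  over generations. With `standardize_each_generation = FALSE` the founder
  scaling is reused and the drift is observable.
* **Generations**: one offspring generation by default, ten when
  `am_rho > 0` so mating-induced correlations approach equilibrium.
* **Genetic correlations between samples**: imperfect correlation is
  realized through correlated per-sample direct-effect vectors; each sample's
  phenotypes use its own vector. Since at most one of the two correlations
  may differ from 1, the vectors are built exactly as
  $rg\,u + \sqrt{1-rg^2}\,v$ around a shared base vector.
* **AM + GN interaction**: with both active, a positive covariance between
  direct and nurture factors emerges across generations. The environmental
  variance is *not* rescaled to force $\mathrm{Var}(Y) = 1$; the realized
  variance is reported through the simulated phenotypes, and the target
  coefficient (below) absorbs the covariance. This is why the between-family
  target rises with assortative mating when nurture is present.
* **Founders** have no nurture term (their parents are not modeled); their
  environmental variance is $1 - h^2$.

The **target coefficient** (`true_target_coefficient()`) is, between
families, the slope of $Y$ on the standardized latent additive SNP factor
$\sum_j (b_j + c_j)\,g_{ij}$ in the prediction sample, where $b_j$ and $c_j$
are the phenotype-scale per-allele direct and nurture effects — the
infinite-GWAS-limit PGI. Under random mating its expectation is
$\sqrt{h^2 + n^2/2}$ (0.5 in the default designs). Within families the
target is the direct effect, $\sqrt{h^2}$.

## GWAS, PGIs, and GREML

`run_gwas()` is the canonical between-family GWAS: one randomly chosen
sibling per family, per-SNP simple regression of the standardized phenotype
on allele count with classical standard errors, vectorized in compiled code.
Monomorphic SNPs get an infinite standard error and are excluded from PGI
weights. `meta_analyze()` combines two summary-statistic sets by fixed-
effects inverse-variance weighting (equal to sample-size weighting at the
equal-$N$ design here; inverse variance is the general rule).
`build_pgi()` forms the weighted allele-count sum and `standardize()`
standardizes it in the analysis (prediction) sample, with the $N-1$ standard
deviation divisor.

`greml_h2()` estimates $h^2_{SNP}$ by restricted maximum likelihood for
$Y \sim N(\mu 1,\ \sigma_g^2 A + \sigma_e^2 I)$ with the GRM
$A = ZZ'/M$ from column-standardized genotypes (`compute_grm()`). The GRM is
eigendecomposed once, the data rotated, and the restricted likelihood
profiled over $h^2 \in [0,1]$ to tolerance $10^{-6}$; the standard error
comes from the numeric curvature of the profiled restricted log-likelihood.
A dense-matrix grid search serves as the test oracle for this routine.
Individuals with pairwise relatedness above 0.05 are removed by greedy
pruning (`prune_related()`) before estimation — in a sibling-pair cohort
this keeps one sibling per family, so the harness also exposes a direct
`one_sib` path that simply takes the first sibling of each family; the two
are distributionally equivalent there and the latter skips the full-cohort
GRM, which is the dominant cost in large prediction samples. Estimated
heritabilities below 0.01 are flagged and excluded from scenario averages,
since the Delta-method standard error explodes as $\hat h^2 \to 0$.

## Clustering and fixed effects

Between families both siblings enter the estimation sample and standard
errors are clustered on the family (CR1 small-sample adjustment); in the
stacked ORIV system, clustering is on the individual, who appears in both
stacks. Within-family fits demean within family (OLS) or family-by-stack
cell (ORIV) — numerically identical to dummy-variable fixed effects, which
the tests verify on small instances — and cluster two-way on individual and
family by inclusion–exclusion. Because each individual belongs to exactly
one family, the two-way formula collapses to family-level clustering; it is
implemented generally nonetheless. The first-stage F reported with ORIV is
$r^2(N-2)/(1-r^2)$ with $r$ the between-family PGI correlation; the same
between-family $r$ is used to scale the PGIs in within-family runs.

## Scenario harness and desk-scale sizes

`run_scenario()` chains the full pipeline per replication with seeds
`base_seed + r`, and `summarize_scenario()` aggregates: mean estimate, the
interval mean ± 1.96 × mean SE, the empirical SD, and the RMSE against the
target (satisfying $RMSE^2 = bias^2 + variance$ exactly). `baseline_table()`
arranges the no-nurture, no-AM grid over GWAS and prediction sample sizes.

The reference design uses $M = 5000$ SNPs, $h^2_{SNP} = 0.25$, GWAS sizes
2 × 2000 ("small", meta $R^2 \approx 4.2\%$) and 2 × 16000 ("large",
$R^2 \approx 15.4\%$), and prediction samples of 1000–16000 individuals,
with 100 replications. The package's own test suite reproduces that table at
desk scale: 100 and 80 replications for the small-GWAS cells with prediction
samples of 1000 and 4000, and 6–20 replications for the remaining cells,
where the per-replication Monte-Carlo spread is several times smaller; the
GREML-bearing PGI-RC checks run at 10–100 replications with the prediction
sample at 1000 or 4000, since one eigendecomposition of a pruned 8000 × 8000
GRM per replication is beyond a quick desk run. These counts are problem-size
choices, not statements about the method.

## What the simulations do and do not show

The generator reproduces the features that drive measurement-error bias and
its corrections: finite-GWAS noise in PGI weights, sibling structure,
phenotypic assortative mating, parental genetic nurture, and cross-sample
genetic correlation. It deliberately omits linkage disequilibrium (SNP
effects are drawn independently and SNPs are unlinked), mutation, selection,
variable family sizes, sex differences, sibling-to-sibling social effects,
population stratification, and covariates. Passing tests therefore
demonstrate the estimators' behaviour under the stated data-generating
process, not the performance of any particular empirical PGI pipeline:
real applications add LD-aware weighting, relatedness structure beyond
sibships, and residualization steps that are out of scope here.

Known limitations: GREML standard errors in very small pruned samples
(a few hundred individuals) are themselves noisy, which is the reason for
the $\hat h^2 < 0.01$ drop rule; ORIV is biased when both GWAS and
prediction samples are small (bias roughly proportional to the inverse
first-stage F); and under simultaneous assortative mating and genetic
nurture the realized phenotypic variance exceeds 1 slightly, so reported
coefficients are on the realized, not renormalized, scale.

## A minimal session

```{r, eval = FALSE}
library(pgicorrect)

cfg <- scenario_config(n_gwas_total = 4000, n_pred = 4000, seed = 1)
sim <- simulate_study(cfg)
pgis <- build_study_pgis(sim)
y <- standardize(sim$pred$phenotype)

ols_pgi(y, pgis$pgi_meta_st, sim$pred$family)     # attenuated benchmark
oriv(y, pgis$oriv_set, family_id = sim$pred$family)
h2 <- greml_prediction_sample(sim)
fit <- ols_pgi(y, pgis$pgi_meta_st, sim$pred$family)
pgi_rc(fit$beta, fit$se, h2$h2_hat, h2$se_h2)
```
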