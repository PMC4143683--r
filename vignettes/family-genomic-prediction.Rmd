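---
title: "Predicting additive genetic contributions in families: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting additive genetic contributions in families: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`famgp` implements a whole-genome prediction workflow for a repeated-measures
quantitative trait (the motivating case is systolic blood pressure) observed
in large multi-generation families. This vignette is the package's account of
the underlying models, the parameters that matter, the synthetic-data
generator that stands in for restricted family data, and the design decisions
taken where more than one reasonable choice existed.

## The two-stage model

**Stage 1 — repeatability animal model.** The observed trait is modelled as

$$ y = X\beta + Zu + Tc + e, \qquad
   u \sim N(0, A\sigma_u^2),\; c \sim N(0, I\sigma_c^2),\;
   e \sim N(0, I\sigma_e^2), $$

where $y$ stacks all visits of all individuals, $X$ carries an intercept and
five covariates (exam year, age, sex, medication use, smoking), $Z$ and $T$
are identical incidence matrices linking records to individuals, and $A$ is
the pedigree additive relationship matrix. $u$ is the additive genetic
contribution (breeding value), $c$ the permanent-environmental effect — the
part of an individual's environment that is constant across that
individual's repeated visits and independent between individuals. Omitting
$c$ on repeated-measures data lets within-individual covariance masquerade as
genetic covariance and inflates $\hat\sigma_u^2$; the test suite demonstrates
this on simulated data. Narrow-sense heritability is
$h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_c^2 + \sigma_e^2)$.

**Stage 2 — whole-genome regression.** The fitted $\hat u$ becomes the
response of

$$ y' = \mu + Ma + e', $$

with $M$ the (column-centred) dosage matrix of the training individuals.
Under GBLUP all marker effects share one variance, fixed relative to the
residual by the genomic-to-residual ratio $\sigma_a^2/\sigma_{e'}^2 = 2/3$;
this is exactly ridge regression / the mixed-model equations, and the package
carries both a Gibbs sampler and a closed-form solver (the latter doubles as
an independent oracle in the tests). Under BayesC$\pi$ each marker effect is
zero with probability $\pi$ and $N(0, \sigma_a^2)$ otherwise; $\pi$ has a
Uniform(0,1) prior (Beta full conditional), the variances scaled
inverse-chi-square full conditionals. Predicted genomic values are
$\hat y' = \mu + M_{\text{new}} \hat a$ with training-mean centring applied
to new genotypes, so an all-zero genotype row does *not* predict $\mu$
exactly — it predicts $\mu$ minus the centred contribution.

## What the synthetic-data generator emulates

Real family whole-genome data of this kind is access-restricted, so the
package generates its own, with the statistical structure the models assume:

* **Pedigree**: 20 disjoint families, 5 non-overlapping generations, 3
  founder couples per family; each mating has $1+\mathrm{Poisson}(\bar k-1)$
  children ($\bar k = 2.2$) and each child marries a newly introduced founder
  spouse with probability 0.5. This yields roughly 900–1100 individuals with
  more members in generations 1–3 (training) than 4–5 (testing), matching
  the family-study regime the validation designs assume. The marriage
  probability and founder-couple count are fixed design constants; only the
  family count, depth and fertility are exposed in `sim_config()`.
* **Genotypes**: founder allele frequencies are drawn uniformly from
  [0.05, 0.5] for common markers and log-uniformly from (1e-4, 0.05) for
  rare ones — a 1/x site-frequency spectrum dominated by very rare alleles,
  so a sizeable fraction of rare markers comes out monomorphic and is
  dropped, as in sequencing data (defaults 800 and 2000 markers over 5
  chromosomes). Genotypes are then gene-dropped: each offspring
  receives one allele per parent, sampled fairly at heterozygous loci.
  Markers are **unlinked** — there is no recombination map and no LD decay.
  The LD-pruning stage is therefore exercised with explicitly duplicated and
  correlated columns in the tests, not with simulated LD.
* **Phenotypes**: true breeding values are marker-driven — 390 causal
  markers (14% of the panel, the polygenicity regime of a complex trait
  like blood pressure) receive $N(0,1)$ effects and the genetic score is centred and rescaled so
  its sample variance equals $\sigma_u^2$ exactly (with `n_causal = 0` the
  generator falls back to a purely polygenic $u \sim N(0, A\sigma_u^2)$).
  Defaults $(\sigma_u^2, \sigma_c^2, \sigma_e^2) = (44.4, 61.5, 135.0)$ give
  $h^2 = 0.18$ and phenotypic variance 240.9. Visit counts are uniform on
  1..4; covariates follow simple fixed distributions (year = visit index,
  age increasing down generations and across visits, sex from the pedigree,
  Bernoulli(0.2) medication and smoking), with SBP-plausible coefficients
  and a baseline of 120 trait units.

Passing tests on these data show the *machinery* is right — estimators
recover generative truths, samplers match closed forms, validation designs
produce the expected ordering. They do not show that real blood-pressure
data has this architecture: real rare variants are clustered and in LD, the
causal architecture is unknown, and real covariate effects are not linear by
fiat. A truth sidecar (`truth.json`) is written for tests only and never
read by the pipeline.

## REML: algorithm and numerical choices

The repeatability model is fitted by REML on the mixed-model equations with
the permanent-environmental block absorbed (it is diagonal), so each
iteration factorizes a $(p+q)$ system, $q$ = number of individuals. The
first 3 iterations are EM-REML updates (monotone, slow); thereafter
average-information (AI) Newton steps are attempted with step-halving, a
component pushed past zero clamped toward the boundary ($\theta/10$, floor
$10^{-8}$), and EM as the fall-back whenever an AI step would decrease the
restricted likelihood. Convergence is declared when every component's
relative change falls below $10^{-6}$, or when the restricted likelihood is
stationary (relative change $<10^{-7}$ over three consecutive iterations) —
the latter matters when a variance sits on the zero boundary, where the
likelihood is flat while the parameter still creeps. The iteration cap is
500; a fit that hits it is flagged `converged = FALSE`, never silently
accepted. The tests check the full surface against an independent direct
$V$-matrix likelihood maximized with `optim`.

Two modelling conventions the data do not dictate: the fixed-effect design
uses a global intercept plus the five covariates as supplied (numeric or
binary; exam year is not expanded categorically, though the covariate set is
configurable), and $A$ covers *all* pedigree members, phenotyped or not —
individuals with phenotype but no genotype still contribute to Stage 1, and
the genomic stages subset $\hat u$ afterwards.

## Marker preparation

* **MAF stratification** uses the inclusive boundary: common is
  MAF $\ge 0.05$, rare is $0 <$ MAF $< 0.05$; monomorphic markers are
  dropped and counted. MAF is computed over the analysis individuals, not
  the founders (a deliberate choice where either reading is defensible; the
  founder spectrum is stored separately in the map).
* **LD pruning** runs on the founders only (the unrelated stratum), as a
  dialect of PLINK's `--indep-pairwise`: windows of 50 markers advancing by
  5, greedy removal of the lower-MAF member of any pair with $r^2 \ge 0.9$
  (ties: the later position loses), monomorphic-on-founders markers removed
  first because their $r^2$ is undefined.
* **Rare-variant collapsing**: per chromosome, position-sorted rare markers
  are cut into blocks of 100; a final block of fewer than 2 markers is
  merged into its predecessor. Individuals are clustered on each window's
  dosage vectors by k-means with $k=3$, k-means++ initialization, 10
  restarts keeping the lowest within-cluster SSE, 300-iteration cap, all
  seeded. Cluster sizes are ranked: largest $\to$ 0, middle $\to$ 1,
  smallest $\to$ 2, size ties broken by ascending centroid norm so the
  coding is deterministic and depends only on the converged partition, not
  on cluster labels. Windows with fewer than 3 distinct dosage vectors use
  as many clusters as exist (one cluster codes everyone 0). The window-size
  sweep (10, 25, 50, 100) shows the count of still-rare collapsed SNPs
  shrinking as windows widen — the basis for operating at 100. Windows
  reset at chromosome boundaries only; nothing finer (e.g. genes) is
  available to the generator.

## Samplers and validation

Both Gibbs samplers run 12,000 iterations, 2,000 burn-in, thinning 10 (1,000
kept samples) by default, seeded through R's RNG so runs are reproducible.
The chain-length tests show a 40,000-iteration chain and three independent
12,000-iteration chains give the same test-set correlations within
Monte-Carlo error. BayesC$\pi$ hyperpriors are scaled inverse-chi-square
with $\nu = 4.2$ and scales matching half the variance of $y'$ (residual)
and half spread over the expected included markers (genetic), a standard
default; $\pi$ starts at 0.9. Collapsed SNPs enter the samplers exactly like
common SNPs — the 0/1/2 codes are taken at face additive value.

Validation: the within-family design trains on generations 1–3 and tests on
4–5; the across-family design ranks the 20 families by genotyped size and
randomly assigns each block of five to the five folds, so every fold holds
one family per size stratum. Across-family summaries are unweighted means
over folds (pooled correlations would weight folds by size; the choice is
documented, not forced by anything). Accuracy is the Pearson correlation and
MSE between $\hat u$ and $\hat y'$. Blending regresses $\hat u$ of
within-family test individuals with at least one training parent on the
genomic prediction, the parent average
($\hat u_p = \hat u_F$, $\hat u_M$, or their mean, per parent availability),
and both; the combined $R^2$ is never below either single predictor's by
nesting. Test individuals without a training parent are excluded from
blending only, not from accuracy.

## Problem sizes used by the tests

The default generator (20 families, ~2,800 markers) is used wherever the
claim concerns the study design itself: variance-component recovery averages
10 replicates; the within-versus-across ordering is checked over 5 seeds
with 1,500-iteration chains (the ordering is a posterior-mean property that
stabilizes long before the default chain length); chain-length robustness
uses the full 12,000/2,000/10 and 40,000/5,000/10 settings. Oracle
equivalences (ridge closed form, exhaustive-partition k-means, gene-drop
Monte Carlo at $10^4$ replicates, direct REML likelihood) run on instances
small enough for the oracle to be exact.

## Known limitations

* No LD, no genotyping error, no missingness, no assortative mating in the
  generator; pruning is structurally exercised but not stress-tested.
* The repeatability model is single-trait, additive-only: no dominance,
  maternal effects or genotype-by-environment terms.
* GBLUP's variance ratio is fixed, not estimated; BayesC$\pi$'s estimated
  $\pi$ is the route by which sparsity is learned.
* `accuracy()` needs at least 3 aligned pairs and flags zero-variance
  inputs rather than manufacturing a correlation.
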