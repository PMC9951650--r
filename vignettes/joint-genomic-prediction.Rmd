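---
title: "Joint multi-population genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multi-population genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, what the synthetic-data generator does and
does not emulate, the numerical choices inside the REML machinery, and the
design decisions that were genuinely open.

## The problem

Two breeding organisations each maintain a genotyped reference population
for the same trait. The trait is expressed in different environments
(climate, management, trait definition), the pseudo-phenotypes are on
different scales, and their reliabilities differ systematically — one
population consists of progeny-tested bulls with reliabilities above 0.9,
the other is dominated by records around 0.4–0.66. The question is whether
a joint reference improves genomic prediction for either population, and
how the answer depends on the between-population genetic correlation.

## Models

**Single-trait weighted GBLUP.** `y = 1μ + Zg + e` with
`g ~ N(0, G σ²_g)` and `e ~ N(0, D σ²_e)`. The response is a de-regressed
proof (DRP); `D = diag((1 − r²_i)/r²_i)` gives low-reliability records more
residual variance. The only fixed effect is an overall mean: herd, year and
parent-average effects are taken to be absorbed upstream in the
de-regression that produced the DRP. `G` is VanRaden's method-1 genomic
relationship matrix.

**Two-trait (joint) GBLUP.** The same trait in the two populations is
treated as two genetically correlated traits with `[g1; g2] ~ N(0, G0 ⊗ G)`
and independent within-population residuals. Every genotyped individual
gets a direct genomic value (DGV) for both traits; a validation animal is
always read off on its own population's trait. Structural missingness (each
animal has a record for at most one trait) is what lets information flow
between populations only through the genetic covariance `σ_g12 G`.

**Residual variances.** The two populations express the trait on different
DRP scales (one population's proofs are standardized, the other's are
deviations from a base population), so the package fits one residual
variance per population by default. A single shared residual — the literal
reading of a model with one `σ²_e` symbol — is available via
`shared_residual = TRUE`, but is indefensible across scales and not the
default.

## REML

Variance components maximize the restricted likelihood
`−2ℓ_R = log|V| + log|X′V⁻¹X| + y′Py`. The record-space covariance `V` is
linear in the parameters, which the average-information (AI) algorithm
exploits: the update is `θ ← θ + AI⁻¹ ∇ℓ_R` with
`AI_ij = ½ y′P V_i P V_j P y`.

Numerical choices, in order of importance:

* **EM fallback.** An AI step is accepted only if it does not decrease
  `ℓ_R`; otherwise the step is halved up to four times, and if still
  unsuccessful the iteration falls back to a true EM-REML update computed
  from the mixed-model-equation inverse. EM steps are monotone by
  construction, so the accepted likelihood trace never decreases (this is
  asserted in the tests). The first iteration is always EM, which makes the
  start robust to a poor initialisation.
* **Parameter space.** Variances are floored at `1e−8 × var(y)` (per trait
  scale) and the genetic covariance is clamped to
  `|σ_g12| ≤ 0.999 √(σ²_g1 σ²_g2)`, keeping `G0` invertible throughout.
  Proposals outside the space are projected onto it rather than discarded,
  so boundary solutions (a variance that truly wants to be zero) are
  reached quickly and reported with a warning.
* **Initialisation.** Half the per-trait response variance for each of
  `σ²_g` and `σ²_e`, zero genetic covariance.
* **Convergence.** Maximum relative parameter change below `tol`
  (default `1e−8`), capped at `max_iter = 200` iterations; non-convergence
  returns the last iterate flagged `converged = FALSE`.
* **Standard errors.** The inverse AI matrix at the optimum approximates
  the parameter covariance; the genetic correlation's SE follows by the
  delta method. Tests check these SEs sit within a factor two of the
  across-seed empirical spread.
* **Mixed-model equations.** Solved dense by Cholesky; the GRM carries a
  configurable ridge `ε I` (default `1e−6`) because no pedigree matrix
  exists here to blend with. Individuals without records stay in the
  equations and receive DGV through `G`.

## The simulator

The generator emulates the study conditions the package is designed around:

* two populations drift from a common founder pool (founder allele
  frequencies uniform on (0.05, 0.5)) through 20 non-overlapping
  generations of binomial sampling at effective size 100, giving F_ST of
  about 0.1 and the characteristic ordering *between-population genomic
  relationship below both within-population means*;
* SNP effects correlated `r_g` across populations
  (`a2 = r_g a1 + √(1 − r_g²) ε`), then rescaled so each population's true
  breeding values have its configured additive variance (defaults 100 and
  25 — deliberately different scales). Correlating effects at the SNP level
  makes the bivariate model's genomic correlation the estimand by
  construction;
* DRP are `tbv + e` with `e ~ N(0, σ²_g (1 − r²)/r²)`, so the model's
  residual weights are exact and the fitted `σ²_e` estimates `σ²_g`;
  reliabilities are fixed (defaults 0.55 and 0.94 for the low- and
  high-reliability population) or Beta-distributed; they are capped at
  0.999 because the weight `(1 − r²)/r²` vanishes at `r² = 1`;
* true breeding values are centered per population before DRP generation,
  because the models fit only an overall mean per trait;
* birth years are uniform over a configurable range (all simulated
  individuals form one sampled cohort, so there is no generation structure
  to respect), which is what the forward cutoff-date split needs;
* genotype calls are masked missing at a configurable rate (default 2%).

What the simulator does **not** emulate: linkage disequilibrium within
chromosomes (SNPs are exchangeable, there is no map), pedigree structure,
selection, the de-regression procedure itself, or migration after the
split. Passing tests therefore demonstrate correctness of the estimation
and validation machinery under the stated generative model, not that real
multi-population data will show the same effect sizes — in real panels LD
consistency between populations, not just relationship structure, drives
the joint gain.

## Quality control

Per population, SNPs with minor allele frequency below 0.01 (strict) are
removed first, then SNPs with call rate below 0.90 (strict); the surviving
panel is the intersection across populations because the joint `G` needs
one panel. Individuals with call rate below 0.90 are removed afterwards.
Remaining missing calls are imputed from pooled observed allele
frequencies (rounded expectation, or a seeded Hardy–Weinberg draw). An
LD-based phasing imputer and its accompanying imputation-accuracy filter
are out of scope; at the simulator's missingness rates the choice is
immaterial, and there is no equivalent of a model-based imputation-R²
metric for frequency imputation, so no such filter is applied.

Allele frequencies for the GRM are observed frequencies pooled over all
genotyped individuals in the analysis, computed once per experiment; one
`G` serves the own-, cross- and joint-reference scenarios so that all three
are compared on the same relationship matrix.

## Validation designs and statistics

The forward split takes, per population, the youngest ~1/5 of phenotyped
individuals (ties on birth date broken by id order) as validation. The
cross-validation design is stratified by population (fold sizes within a
population differ by at most one), with replicate `r` seeded as
`seed + r`; 5 folds and 10 replicates by default.

Accuracy is `acc = cor(DRP, DGV) / r̄`. The package defines `r̄` as the
mean of `√r²_i` over validation animals — the literal "averaged accuracy
of the DRP" — and offers `rbar_mode = "sqrt_mean"` for the alternative
convention, since published reports rarely say which was used. Accuracy
can exceed 1 under either convention. Unbiasedness is the regression of
DRP on DGV; sample covariance and variance share one denominator so the
ratio is convention-free.

Variance components are re-estimated on the reference records of every
split and scenario (never carried over from the full data), which costs
compute but excludes validation-to-reference leakage by construction; the
tests additionally audit the reference sets of every fit and verify that
perturbing validation records leaves the fitted models bit-identical.

## Problem sizes used in the tests

The package's test suite exercises the full pipeline at reduced scale,
chosen to keep each property comfortably measurable: oracle-equivalence
checks on instances up to 30 individuals (tolerance `1e−8` against dense
GLS/BLUP closed forms); grid-search REML verification at n = 8; genetic
correlation recovery at 2 × 400 individuals, 1000 SNPs, reliabilities
0.9/0.6, 20 seeds per true `r_g` in {0.15, 0.45, 0.72}; and the
directional own/cross/joint comparisons at 2 × 300 individuals, 1500 SNPs
over 10 seeds, at `r_g` 0.7 (joint gain expected for the low-reliability
population) and 0.15 (no material joint gain expected).

## Known limitations

* Exchangeable SNPs mean the simulator cannot express differences in LD
  consistency between populations — the main real-world moderator of joint
  gains.
* Dense linear algebra bounds practical problem sizes at a few thousand
  genotyped individuals; the study-scale designs of tens of thousands of
  animals would need sparse or iterative solvers.
* Only two populations and one trait at a time; multi-trait extensions of
  `G0` beyond 2 × 2 are out of scope.
* The AI-REML SEs are asymptotic; at the test scales they are only checked
  to be the right order of magnitude.
* At a few hundred reference records per population with low reliabilities,
  the genetic-correlation estimate of the joint model is very noisy (SEs of
  0.3–0.7). A consequence worth knowing: when the true correlation is low,
  the joint model's accuracy for the low-reliability population fluctuates
  by a few points either way around the own-reference accuracy purely
  through `r_g` estimation error — equivalence between joint and own
  prediction at a 1-point margin is only resolvable at reference sizes in
  the thousands, which is where the original comparison was made.
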