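---
title: "Interacted QTL mapping and hybrid prediction in partial NCII designs"
author: "NCIIqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interacted QTL mapping and hybrid prediction in partial NCII designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NCIIqtl)
```

## The problem

Hybrid breeding programs in crops such as rapeseed, rice and maize cross one
group of inbred parents (e.g. cytoplasmic male-sterile lines) to a second
group (fertility restorer lines) — the North Carolina design II. In practice
only a small subset of the factorial is realized ("partial" NCII). Mapping
quantitative trait loci in such a population is attractive because the
population is the breeding material itself, but it poses two problems that
this package addresses jointly:

1. **The full genetic model is oversaturated.** With `m` biallelic markers,
   the model with all additive (`a`), dominance (`d`) and pairwise
   interaction (`aa`, `ad`, `da`, `dd`) effects contains
   `2m + 2m(m-1)` candidate effects. For `m = 205` that is
   410 main + 83,640 interaction = 84,050 effects — two orders of magnitude
   more than a typical population of a few hundred lines.
2. **Breeding decisions need complete hybrid tables.** General and specific
   combining abilities (GCA/SCA) are only defined on the full factorial, but
   most crosses were never made.

## Genetic model and coding

For individual `i` the trait is modeled as

```
y_i = mu + sum_j (x_ij a_j + z_ij d_j)
         + sum_{j<k} (x_ij x_ik (aa)_jk + x_ij z_ik (ad)_jk
                      + z_ij x_ik (da)_jk + z_ij z_ik (dd)_jk) + e_i
```

with `e_i ~ N(0, sigma^2)`. Genotype codes count copies of the per-marker
reference allele (0/1/2). The dummy coding is F-infinity style: `x = code - 1`
(-1/0/1) and `z = 1` for heterozygotes, else 0. Two consequences of this
coding are worth noting because they are observable in results:

* every dominance-type column is identically zero on inbred parents, so a
  parents-only population can only ever yield `a` and `aa` effects;
* a dominance-type column takes 2 values and an additive or product column
  takes up to 3, which fixes the degrees of freedom of the screening tests
  below (df = 1 vs df <= 2).

`ad(j,k)` places the additive part at the first-named locus and the dominance
part at the second; `ad(j,k)` and `da(j,k)` are distinct effects. Interaction
terms here are *statistical* interactions of the coded main columns, not
orthogonalized (Cockerham-style) epistasis; with non-equal allele frequencies
the main and interaction columns are correlated, and the package makes no
attempt to orthogonalize them.

Missing genotype codes are excluded observation-wise during screening and
mean-imputed (column mean of the observed dummies, i.e. `2p - 1` on the
additive scale and the observed heterozygote frequency on the dominance
scale) when model-matrix columns are materialized for estimation.

## Stage 1 — bulked-segregant chi-square screening

Because 84,050 effects cannot enter one model, candidate effects are first
screened on extreme-phenotype pools (`selectExtremes()`): the
`floor(0.10 n)` highest and lowest phenotyped individuals (72 per tail at
n = 725), parents and F1 pooled, ties at the boundary broken by ascending id.
For every candidate effect an `L x 2` contingency table is formed between the
distinct observed values of its dummy column (L <= 3) and pool membership,
and Pearson's chi-square without continuity correction is computed
(`chi2Independence()`, vectorized over all effects in `screenTopEffects()`).
Expected counts are not floored; the asymptotic test is used as-is. Up to
`K = 100` main and `K = 100` interaction effects with the smallest P-values
pass to estimation, subject to a raw entry threshold `alpha = 0.05` — the cap
mirrors the method's published workflow, and the threshold prevents late
iterations from admitting pure noise once the strong signal has been
corrected away. Effects already accumulated in earlier iterations are never
re-screened.

The contingency rows are the values of the *effect column* (so an `aa` table
uses the product-coded classes, not the 9 two-locus genotype classes). This
choice uniquely reproduces the df pattern of the six effect kinds: `d`/`dd`
always give df = 1, the others df <= 2.

## Stage 2 — empirical Bayes shrinkage (EM)

The selected columns `Z` enter `Y = X beta + Z gamma + e` with `X` a column
of ones (`beta` is the population mean). Each effect has a normal prior
`gamma_k ~ N(0, sigma2_k)` and each `sigma2_k` a scaled inverse chi-square
prior with hyperparameters `(tau, omega) = (0, 0)`. `fitEmpiricalBayes()`
iterates:

* **E-step** `E(gamma_k) = sigma2_k Z_k' V^{-1} (Y - X beta)`,
  `var(gamma_k) = sigma2_k - sigma2_k Z_k' V^{-1} Z_k sigma2_k`, with
  `V = sum_k Z_k Z_k' sigma2_k + I sigma2`;
* **M-step** `sigma2_k = [E(gamma_k'gamma_k) + omega] / (tau + 2 + 1)`,
  `beta = (X'V^{-1}X)^{-1} X'V^{-1}Y`, and
  `sigma2 = (Y - X beta)'[Y - X beta - sum_k Z_k E(gamma_k)] / n`.

Numerics: all `V^{-1}` products are computed through the q x q Cholesky
factor of `sigma2 I_q + D^{1/2} Z'Z D^{1/2}` (algebraically identical to the
dense n x n route, and safe when variance components reach zero). Convergence
is declared when the largest absolute change over `(beta, sigma2, sigma2_k)`
falls below 1e-6 (cap 1,000 iterations); each `sigma2_k` is floored at 1e-10,
and an effect whose posterior mean ends below 1e-6 in absolute value is
reported as exactly zero and excluded downstream. Initial values are
`beta = mean(Y)`, `sigma2` the population variance of `Y`, and
`sigma2_k = 1`. No standardization of `Z` is applied: effects are reported on
the coded scale, as in the published tables.

**A note on likelihood monotonicity.** This EM maximizes the *posterior* of
the variance components — the marginal likelihood of `Y` *times* the
`(sigma2_k)^{-1}` prior density (the origin of the divisor
`tau + 2 + 1 = 3`). The bare marginal likelihood is therefore not a Lyapunov
function of the iteration: when a moderate effect's variance component is
shrunk toward the floor, the algorithm deliberately trades marginal
likelihood for prior mass, and the marginal log-likelihood trace (stored in
`logLikTrace`) can decrease by a few tenths. The penalized objective
`logL - sum_k log(sigma2_k)` is non-decreasing up to small (~1e-3)
violations introduced by the residual-variance update, which omits the
posterior-variance trace term a textbook EM M-step would carry. The package
implements the published update verbatim and records the trace so users can
inspect it.

## Stage 3 — likelihood-ratio (LOD) test and iteration

Each effect retained with a non-zero estimate is tested by a profile-style
likelihood ratio: the converged model's marginal log-likelihood versus the
same model with that one effect removed (`sigma2_k = 0`, hence
`gamma_k = 0`), all other parameters held fixed — no refit. `LOD =
LR / (2 ln 10)`; the significance cutoff is the conventional `LOD >= 2.0`
(boundary inclusive). Holding the other parameters fixed is cheap and
deterministic and matches the two-stage testing style this method builds on;
refitting the reduced model would only lower its likelihood less, so the
fixed-parameter variant is the more conservative reading.

The outer loop (`runScan()`) alternates screening, shrinkage and testing with
phenotype correction `y' = y - W b`, where `W` and `b` are the columns and
estimates of the *newly* significant effects of the current iteration
(previously corrected effects are not re-subtracted). The loop stops when an
iteration contributes nothing (cap 20). Finally all accumulated effects are
re-fitted jointly on the *original* phenotype, and only effects passing
`LOD >= 2` in that joint model are reported, main effects first and then
interactions, each ordered by their screening P-value. Each reported QTL
carries its screening chi-square and P-value, LOD, shrinkage estimate and
`r^2 = 100 Var(w gamma) / Var(y)` (population-variance convention).

## Hybrid prediction and combining abilities

`predictHybridTable()` evaluates every parentA x parentB cell: the F1
genotype at each QTL marker is the parental mean code (inbred parents), the
detected effects are evaluated on the resulting dummies, and the cell value
is `mu + sum_k w_k gamma_k`. Observed F1 phenotypes replace predictions where
a cross was realized (`useObserved = TRUE`, the default — the table then
mixes measured and predicted values, which is also how the grand mean and
combining abilities are intended to be read). A parent with a missing code at
a QTL marker is imputed from the parental allele frequency with a warning.

`combiningAbilities()` decomposes the complete table as
`v_ij = grand mean + GCA_i + GCA_j + SCA_ij` with unweighted row/column
means; GCA vectors and all SCA rows/columns sum to zero and the
reconstruction is exact by construction. `rankElites()` ranks parents by GCA
and crosses by the hybrid value itself (with SCA reported alongside), ties
broken by id.

## The Monte Carlo simulator

`simulationSpec()` + `simulateNCII()` emulate the study conditions: inbred
parent genotypes drawn per marker as code 2 with probability equal to the
reference-allele frequency (default 0.5 at every marker — the original
marker panel is not public, so the simulator synthesizes genotypes rather
than reusing real ones); a partial pedigree built by cycling the parentB
lines, each drawing two distinct random parentA mates, until the requested F1
count is reached; F1 genotypes deduced from the parents; and phenotypes
`y = mu + sum_i e_i w_i + N(0, sigma2 = 1)`.

The default architecture is eight QTL — two `a`, two `d`, one each of `aa`,
`ad`, `da`, `dd` — all located on markers, each with the same heritability.
Effect sizes are calibrated per population: `sigma2_G = h2 sigma2 /
(1 - sum h2)` and `e = sqrt(sigma2_G / Var(w))` with `Var(w)` the realized
population variance of the QTL's dummy column, so each QTL explains exactly
its target share of variance in that replicate. Signs default to positive.

Two design choices matter for interpreting experiments:

* **Common random numbers.** Replicate `i` of any condition uses seeds
  derived as `baseSeed + 7919 i` (genotypes/pedigree) and an offset constant
  for residuals, and parents are drawn in a fixed order, so conditions that
  share a replicate index share genotypes and noise as far as the structure
  allows. Power comparisons across heritability or sample-size levels are
  therefore paired, which is what makes monotone-trend checks meaningful at
  20 replicates.
* **Variance decomposition is exact marginally, not jointly.** Calibration
  fixes each QTL's own variance share. In a mixed parents + F1 population
  the dominance-type columns are all zero on parent rows, which induces
  positive correlations (about 0.4 between `z` columns at distinct markers at
  the default structure) and inflates the total phenotypic variance by
  roughly 15% over `sigma2 / (1 - sum h2)` under the default architecture.
  In an all-F1 population the columns are independent across markers and the
  clean decomposition holds.

`runExperiment()` scans each replicate, matches reported effects to the truth
by exact descriptor identity, and reports per-QTL power (fraction of
replicates with `LOD >= 2`), the mean and SD of the absolute estimation bias
among detecting replicates, and the false positive rate with denominator
`2m + 2m(m-1) - nQTL` zero effects per replicate (84,042 at m = 205).

### What the simulations do and do not show

The simulator reproduces the *design* of the study populations: biallelic
markers without linkage, fully inbred parents, deduced F1, i.i.d. normal
residuals, QTL sitting exactly on markers. Real data differ in ways the
tests cannot certify: linked markers, multi-allelic SSRs collapsed to
biallelic codes, genotyping error, non-normal traits, and QTL between
markers. Passing the simulated checks therefore validates the machinery and
its statistical calibration, not field performance on any particular panel.

## Problem sizes used by the test suite

The packaged checks run the trend experiments on a 40-marker panel with 20
fixed-seed replicates per condition (heritabilities 0.02/0.05/0.08 at the
298 + 143 + 284 structure; sample sizes 400/500/600 at 2:1:2; parents-only
at 600), and the null-calibration scan at the full 205-marker density with
20 replicates. These sizes were chosen so the full suite completes in a few
minutes while leaving the qualitative conclusions — power rising with
heritability and sample size, main effects beating interactions, `dd`
weakest, false positive rate well under 0.5% — clearly resolved.

## Known limitations

* Two-locus interactions only; no three-way terms.
* Interaction effects are statistical, not orthogonalized epistasis;
  estimates at correlated columns shift together.
* The LOD threshold 2.0 is a fixed convention, not a permutation threshold.
* GCA/SCA from a mixed observed/predicted table inherit any bias of the
  detected-QTL model; with few detected dominance effects, SCA is mostly
  shrunk toward zero.
* Hybrid prediction assumes inbred, genotyped parents at all QTL markers.
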