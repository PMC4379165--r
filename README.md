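# NCIIqtl

Interacted QTL mapping and hybrid prediction for **partial NCII mating
designs** — populations made of two groups of inbred parents (e.g. sterile
and restorer lines in hybrid rapeseed breeding) plus a subset of their F1
hybrids.

## What it does

For a quantitative trait measured on parents and F1s, the package fits the
full genetic model with every additive (`a`), dominance (`d`) and two-locus
interaction effect (`aa`, `ad`, `da`, `dd`):

    y_i = mu + sum_j (x_ij a_j + z_ij d_j)
             + sum_{j<k} (x_ij x_ik (aa)_jk + x_ij z_ik (ad)_jk
                          + z_ij x_ik (da)_jk + z_ij z_ik (dd)_jk) + e_i

with F-infinity coding (`x` in -1/0/1, `z` = heterozygote indicator) and
`e ~ N(0, sigma^2)`. With `m` markers the model holds `2m + 2m(m-1)`
candidate effects (84,050 at m = 205), far more than individuals, so mapping
proceeds in stages:

1. **Bulked-segregant screening** — Pearson chi-square independence tests of
   every candidate effect between the 10% highest and 10% lowest phenotype
   pools; the top 100 main and top 100 interaction effects (raw p <= 0.05)
   advance.
2. **Empirical Bayes shrinkage** — the selected effects are jointly
   estimated by an EM algorithm with per-effect normal priors
   `gamma_k ~ N(0, sigma2_k)` and scaled inverse chi-square hyperpriors,
   which shrinks noise effects to zero.
3. **LOD testing and phenotype correction** — surviving effects are tested
   by likelihood ratio (`LOD >= 2.0` declares significance), subtracted from
   the phenotype, and the scan repeats until nothing new is found; a final
   joint fit on the original phenotype produces the report.
4. **Breeding by design** — the detected QTL predict genotypic values for
   *all* parent combinations (including crosses never made), from which
   general/specific combining abilities (GCA/SCA) rank elite parents and
   hybrids.

A Monte Carlo simulator of partial NCII populations and a power /
false-positive-rate harness (`simulationSpec()`, `simulateNCII()`,
`runExperiment()`) are first-class parts of the package.

## Worked example

Simulate the default study conditions — 298 + 143 inbred parents, 284 F1
hybrids (n = 725), eight QTL (two `a`, two `d`, one each `aa`/`ad`/`da`/`dd`)
at heritability 0.05 on a 40-marker panel — then scan and rank crosses:

```r
library(NCIIqtl)
spec <- simulationSpec(markers = 40, nParentA = 298, nParentB = 143,
                       nF1 = 284, qtl = defaultQTLArchitecture(40, h2 = 0.05))
pop <- simulateNCII(spec, seed = 1)
pop
#> NCIIPopulation: 725 individuals x 40 markers (trait 'simTrait')
#>   parentA: 298  parentB: 143  F1: 284
#>   realized crosses: 284 of 42614 possible
#>   phenotyped: 725

report <- runScan(pop)
as.data.frame(report)[, c("effect", "kind", "chi2", "p", "LOD",
                          "effectSize", "r2")]
#>         effect kind  chi2        p   LOD effectSize   r2
#> 1       d:M028    d 54.34 1.69e-13  7.52      0.599 3.36
#> 2       a:M012    a 56.07 6.69e-13 14.83      0.363 6.00
#> 3       a:M002    a 30.78 2.08e-07  6.98      0.245 2.78
#> 4       d:M020    d 26.56 2.55e-07 12.08      0.736 5.16
#> 5 aa:M004×M022   aa 16.74 2.31e-04  6.88      0.260 2.74
#> 6 ad:M010×M026   ad 14.46 7.24e-04  7.96      0.809 3.22
#> 7 da:M016×M032   da 14.03 8.98e-04  5.87      0.652 2.33
#> 8 dd:M024×M038   dd  7.34 6.76e-03  7.57      0.779 3.19
```

All eight simulated QTL are recovered: each row reports the screening
chi-square and P-value (df = 2 for 3-level additive/product columns, df = 1
for 2-level dominance columns), the LOD score from the final joint model, the
shrinkage estimate on the coded scale, and the percent phenotypic variance
explained. Hybrid prediction completes the factorial and ranks crosses by
predicted/observed hybrid value (BV), with SCA alongside:

```r
ht <- predictHybridTable(pop, report)
ht
#> HybridTable: 298 parentA x 143 parentB (284 observed, 42330 predicted)
rankElites(combiningAbilities(ht), top = 3)$crosses
#>       parentA parentB    BV   SCA
#> 40405   A0175   B0136 4.690 3.517
#> 964     A0070   B0004 4.636 2.600
#> 36532   A0176   B0123 4.523 2.977
```

## Command line

A thin front end wraps the same functions
(`system.file("scripts/ncii-qtl.R", package = "NCIIqtl")`):

```sh
Rscript ncii-qtl.R simulate --markers 40 --parentA 298 --parentB 143 \
    --f1 284 --h2 0.05 --seed 1 --out-prefix sim/
Rscript ncii-qtl.R scan --genotypes sim/genotypes.csv \
    --phenotypes sim/phenotypes.csv --pedigree sim/pedigree.csv \
    --out report.tsv
Rscript ncii-qtl.R predict --genotypes sim/genotypes.csv \
    --phenotypes sim/phenotypes.csv --pedigree sim/pedigree.csv \
    --report report.tsv --top 10 --out elites.tsv
```

Input formats: `genotypes.csv` (`id,role,<marker...>`, codes 0/1/2, empty =
missing, roles `parentA`/`parentB`/`F1`), `phenotypes.csv` (`id,<trait>`),
`pedigree.csv` (`f1_id,parentA_id,parentB_id`).

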