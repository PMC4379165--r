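Package: NCIIqtl
Title: Interacted QTL Mapping and Hybrid Prediction in Partial NCII Mating Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps main-effect (additive, dominance) and two-locus interacted
    (aa, ad, da, dd) quantitative trait loci in partial North Carolina design II
    (unbalanced factorial) populations of inbred parents and F1 hybrids. The
    oversaturated full genetic model is handled by bulked-segregant chi-square
    screening of candidate effects on extreme-phenotype pools, empirical
    Bayesian EM shrinkage of the selected effects, likelihood-ratio (LOD)
    testing, and iterative phenotype correction. Detected QTL are used to
    predict genotypic values of unrealized F1 combinations and to rank elite
    parents and crosses by general and specific combining ability. A Monte
    Carlo simulator of partial NCII populations and a power / false-positive
    rate evaluation harness are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
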