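Package: cisplast
Title: Cis-Regulatory Evolution of Expression Plasticity from F1 Hybrid
    Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cis-acting regulatory variants from allele-specific
    expression in interspecific F1 hybrids sampled over a stress time
    course, classifies each gene's mode of expression-plasticity evolution
    (orthoplastic or paraplastic basal change crossed with magnified or
    mitigated plastic response), assigns derived versus undetermined cis
    variants by parsimony across two hybrid comparisons, and compares gene
    groups with population-genetic summary statistics (pi, Tajima's D,
    Ka/Ks) under a gene-resampling bootstrap. Includes a synthetic-data
    generator with planted ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    seqinr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
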