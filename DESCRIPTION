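Package: memoqtl
Title: DNA-Methylation-Moderated eQTL Mapping with Nested Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps expression quantitative trait loci whose SNP-expression
    relationship is moderated by the methylation level of a CpG site
    (memo-eQTLs). Implements the three nested Gaussian linear models
    (eQTL, covariate, and moderation models), likelihood-ratio gating of
    the SNP x meCpG interaction, upstream screens (CpG-CTCF occupancy
    correlation, LD pruning, candidate SNP-CpG-gene triple enumeration
    with cis-window and betweenness constraints), downstream sample
    stratification at an optimal methylation threshold with variance
    decomposition, chromatin-loop spatial classification of the
    SNP-CpG-gene locus, and a synthetic-cohort generator with F1-based
    method evaluation and permutation nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
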