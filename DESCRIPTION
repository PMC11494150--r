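Package: heterosisTrio
Title: Expression Inheritance and Heterosis Analysis for Hybrid/Parent
    Trios Under Drought Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq of crop hybrid/parent trios
    across well-watered, water-deficit and re-watering conditions:
    negative-binomial Wald differential expression with a fold-change and
    FDR calling rule, presence/absence expression variation (PAV types
    I-V), inheritance-mode classification (additive, high/low dominance,
    overdominant, underdominant), directional drought and re-watering
    response gene sets with conserved-set intersections across hybrids
    (CDRG/CRRG and the derived DODG/DUDG/RODG/RUDG sets), mid-parent and
    high-parent heterosis indices for phenotypic traits, and hypergeometric
    gene-set over-representation testing. Includes a negative-binomial
    trio simulator with per-gene ground truth so every stage can be
    benchmarked without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
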