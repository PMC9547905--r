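Package: sphingolens
Title: Multi-Omic Interrogation of the Sphingomyelin/Ceramide Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three computational arms for studying sphingolipid metabolism in
    neurodegenerative disease: (1) constraint-based flux analysis on a curated
    sphingomyelin/ceramide pathway network, with expression-guided
    context-specific model extraction (iMAT-style), flux variability analysis,
    and rank-based group comparison of fluxes; (2) a metabolite-ratio screen
    over parsed lipid nomenclature with BIC-based medication covariate
    selection, covariate-adjusted association, and p-gain ranking; and
    (3) gene-based genetic association with exact Hardy-Weinberg variant QC
    and permutation-derived gene-wise empirical p-values. Seeded synthetic
    data generators with planted effects support end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
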