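Package: popdog
Title: Population Structure, Diversity and Selection-Signature Scans for
    SNP-Array Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genotype-based population genetics of multi-breed
    SNP-array panels: PLINK text and binary input/output, quality control,
    per-population diversity indices (polymorphism proportion, rarefaction
    allelic richness, heterozygosity, inbreeding coefficients), identity-by-
    state distances, linkage-disequilibrium decay and r2-threshold
    summaries, run-of-homozygosity detection, an ANOVA-style multi-
    population F_ST estimator, a windowed locus-specific divergence (d_i)
    selection scan with group contrasts, principal-component and neighbor-
    joining structure summaries, frequency-based ABBA-BABA D-statistics
    with block-jackknife standard errors, and a founder-mosaic
    Balding-Nichols genotype simulator providing ground truth for all of
    the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
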