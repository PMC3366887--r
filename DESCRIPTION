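Package: aeiquant
Title: Allelic Expression Imbalance Analysis for Candidate cis-eQTL Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allelic expression imbalance (AEI) from replicate-level
    dual-probe qPCR (FAM/VIC Ct pairs) or primer-extension peak intensities,
    normalising cDNA allelic ratios against genomic-DNA ratios, calling
    imbalance at a fold-difference threshold, and testing measurements with an
    exact Mann-Whitney test that handles ties by full enumeration. Includes
    delta-Ct total-expression analysis with genotype-stratified regression,
    Kruskal-Wallis association of allelic ratios with a marker genotype,
    linkage-disequilibrium utilities, and a synthetic cis-eQTL cohort
    generator (haplotype structure, per-haplotype expression fold change,
    replicate-level measurement noise) for calibration and power studies.
    Ships a transcribed allelic-ratio table from a published osteoarthritis
    candidate-locus study as a worked reproduction fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
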