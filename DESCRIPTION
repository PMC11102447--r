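Package: perturbmap
Title: Fitness Effects of Pooled CRISPRi Perturbations Across a Barcoded Cross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPR interference screens performed
    across a panel of barcoded haploid cross progeny (segregants). Converts
    double-barcode amplicon sequencing reads into chimera-corrected lineage
    count tables, estimates per-lineage relative fitness from trajectory data,
    tests each guide RNA for mean and background-dependent (segregant-specific)
    fitness effects with mixed models, derives per-segregant deviation values,
    decomposes their heritability into broad- and narrow-sense components, maps
    interacting loci with permutation thresholds, and detects hub loci that
    interact with many perturbations. Includes a synthetic-data generator that
    emulates the full experiment (cross genotypes, effect architectures,
    lineage trajectories, multinomial sequencing noise, PCR chimeras, raw
    reads) with retained ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
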