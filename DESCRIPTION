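Package: resistscape
Title: Multi-Omic Annotation of CDK4/6 Inhibitor Resistance in Metastatic Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and integrative annotation of tumor and ctDNA
    profiling data from CDK4/6-inhibitor-resistant hormone-receptor-positive
    metastatic breast cancer. Provides copy-number-above-ploidy (CNAP)
    classification of allelic copy-number segments, biallelic-inactivation and
    clonality calls, a bundled oncogenic-knowledge lookup, single-sample
    gene-set enrichment scoring with reference-cohort quantile categories,
    receptor-balanced PAM50-style intrinsic subtype assignment, a data-driven
    rule engine that labels per-patient resistance mechanisms as known or
    plausible, paired-sample clonal dynamics (acquired and enriched
    alterations, co-existing lineages, convergent evolution), exact
    Mann-Whitney and Fisher association statistics linking genomic drivers to
    transcriptional state and clinical benefit, and a seeded synthetic-cohort
    generator with a planted-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
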