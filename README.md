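# resistscape

Multi-omic annotation of CDK4/6-inhibitor resistance in HR+/HER2- metastatic
breast cancer.

Patients whose tumors progress on a CDK4/6 inhibitor (palbociclib,
ribociclib, abemaciclib) plus endocrine therapy carry a recognizable
landscape of resistance drivers — activating mutations in *ESR1*, *ERBB2*,
*AKT1* or *BRAF*, loss of *RB1*, *PTEN* or *NF1*, high-grade amplifications
of *FGFR1/2*, *ERBB2* or *AURKA*, loss of ER expression, and transcriptional
states such as the HER2-enriched or Basal intrinsic subtype. `resistscape`
implements the post-sequencing analysis layer that turns per-sample mutation
tables, allelic copy-number segments, purity/ploidy estimates and expression
matrices into that annotation, for analysts working on tumor + ctDNA
profiling studies of endocrine/CDK4/6i resistance.

## What it computes

* **Discrete genomic calls.** Copy number above ploidy
  (`CNAP = total_cn - ploidy`) classified as Deep DEL (segment copy number
  < 0.5), GAIN (CNAP > 1.5), AMP (>= 3), High AMP (>= 6) and Focal High AMP
  (>= 9 on <= 100 genes); biallelic inactivation (LOH + loss-of-function
  hit); clonality from cancer cell fraction (clonal iff CCF >= 0.8 by
  default); oncogenic effect and actionability from a bundled knowledge
  snapshot; the acquired (> 6 months on prior CDK4/6i) vs intrinsic
  resistance phenotype; purity >= 8% exome QC.
* **Reference-quantile transcriptional scoring.** Upper-quartile
  normalization, single-sample gene-set enrichment (weighted-ECDF running
  sum, exponent 0.75), range-normalized enrichment scores, and
  decile/quartile categories relative to a receptor-status-labeled
  reference cohort; PAM50-style intrinsic subtype assignment by Spearman
  correlation to subtype centroids after rescaling against an ER-balanced
  reference subsample (Not Classified below rho 0.10).
* **A rule-based mechanism engine.** Per-patient resistance features from
  clinical (ER loss), genomic and transcriptomic calls, with known vs
  plausible evidence per treatment (CDK4/6i, anti-ER), aggregated into
  per-patient verdicts and cohort summaries.
* **Clonal dynamics.** Acquired / enriched / shared / lost calls between
  paired pre- and post-CDK4/6i samples, co-existing lineage detection
  between concurrent tumor and ctDNA samples, and convergent-evolution
  flags.
* **Exact association statistics.** AUC with the Mann-Whitney U it rescales
  (`AUC = U / (n1 n2)`), the exact one-sided permutation tail of U, the
  two-sided Fisher exact test on quartile-dichotomized features, Welch's
  t-test screens across signatures, and trial efficacy proportions
  (CBR = CR + PR + SD >= 24 weeks; DCR = CR + PR + SD >= 12 weeks).
* **A seeded synthetic-cohort generator** with a planted-truth manifest, so
  the full pipeline is testable without controlled-access data.

## Worked example

```r
library(resistscape)

cfg <- sim_config(seed = 42, n_patients = 12, n_genes = 600,
                  n_reference_samples = 60,
                  reference_receptor_counts = c("HR+/HER2-" = 25, "HR+/HER2+" = 8,
                                                "HR-/HER2+" = 3, "HR-/HER2-" = 4))
out <- run_pipeline(cfg)

out$summary$counts
#>                known known_plus_plausible       plausible_only
#>                    9                    1                    2
#>          unexplained
#>                    0

out$associations
#>                   feature           label auc  u       p n_pos n_neg         test
#> 1 ESTROGEN_RESPONSE_EARLY ESR1_activating   1 35 0.00126     7     5 mw_one_sided

out$trial$cbr   # 16.7
out$trial$dcr   # 75

table(vapply(out$subtypes, `[[`, "", "subtype"))
#>  HER2E   LumA   LumB Normal
#>      4      1      6      1

out$lineage[["P01"]]$divergent
#> [1] TRUE
```

Reading the output: all 12 simulated patients had an identifiable resistance
mechanism (9 with known mechanisms for both prior treatments, 1 with a
known + plausible mix, 2 with only plausible features); early
estrogen-response signature activity perfectly separated the planted
*ESR1*-mutant tumors (AUC 1.00, exact one-sided Mann-Whitney
P = 1.3 x 10^-3 at 7 vs 5); two patients carried a second, divergent tumor
lineage visible only in ctDNA. The trial metrics are the simulated cohort's
clinical-benefit and disease-control rates.

Real cohorts enter through the same surfaces: `read_maf()`, `read_seg()`,
`read_expression_tsv()`, `read_gmt()`, `reference_cohort()`, then the same
per-stage functions (`annotate_sample_calls()`, `score_signatures()`,
`pam50_assign()`, `extract_features()`, `compare_paired_samples()`, ...).

## Documentation

The methods vignette (`vignettes/resistance-annotation.Rmd`) describes the
models, thresholds, design decisions and limitations; every exported
function carries roxygen documentation.
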