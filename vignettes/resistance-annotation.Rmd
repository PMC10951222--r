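---
title: "Annotating CDK4/6 inhibitor resistance from multi-omic data: methods and design notes"
author: "resistscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating CDK4/6 inhibitor resistance from multi-omic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistscape)
```

## Scope

`resistscape` annotates resistance to CDK4/6 inhibitors and endocrine
therapy in HR+/HER2- metastatic breast cancer from post-variant-calling
inputs: per-sample somatic mutation tables (gene, protein change, variant
class, cancer cell fraction), allelic copy-number segments, purity/ploidy
estimates, log2(TPM+1) expression matrices, gene sets, and clinical
metadata. Upstream steps — alignment, variant calling, ABSOLUTE-style
purity/ploidy fitting, expression quantification, batch correction,
survival modeling — are out of scope by design.

## Genomic calls

**Copy number above ploidy (CNAP).** Amplification is judged relative to
the sample's genome-wide ploidy: `CNAP = total_cn - ploidy`. Classes, in
precedence order: Deep DEL when the segment's total copy number is below
0.5 (an absolute threshold — a deletion is a deletion regardless of
ploidy); Focal High AMP when CNAP >= 9 on a segment of at most 100 genes;
High AMP when CNAP >= 6; AMP when CNAP >= 3; GAIN when CNAP > 1.5; else
neutral. A CNAP >= 9 event on more than 100 genes is High AMP — the gene
count gates only focality, it does not demote the amplitude call. For
gene-level calls a gene inherits the segment covering it; a gene touching
two segments takes the higher-CNAP one (ties are not distinguished). In
figure-style reports, GAIN/AMP classes are suppressed everywhere and Deep
DELs are additionally suppressed for ctDNA samples, whose deep-deletion
calls are unreliable at typical plasma tumor fractions; the
machine-readable output keeps everything.

**Biallelic inactivation** requires loss of heterozygosity (minor copy
number zero on the covering segment) together with a loss-of-function hit:
either an annotated LOF / likely-LOF effect, or a truncating variant class
(nonsense, frameshift, nonstop). A gene with no covering segment returns a
distinct "no coverage" result (`NA`), never `FALSE`.

**Clonality.** A mutation is clonal when its cancer cell fraction reaches
0.8. No consensus threshold exists for point-estimate CCFs; 0.8 is a
common convention for ABSOLUTE-derived estimates and the parameter is
exposed (`classify_clonality(ccf, threshold)`). Full Bayesian CCF
clustering could classify borderline mutations differently; that machinery
is intentionally not emulated.

**Oncogenic annotation** is a static, bundled snapshot
(`inst/extdata/oncogenic_knowledge.tsv`) rather than a live service, so
results are reproducible offline. Three rule kinds: exact protein-change
matches, positional missense windows (e.g. any *ESR1* 536–538 missense is
activating), and truncating-class rules for tumor suppressors. Unmatched
mutations are VUS. For comma-separated double mutations the strongest
effect wins, and a per-gene multi-hit flag marks genes with two or more
activating hits (the double-*PIK3CA* rule consumes it).

**Resistance phenotype.** Biopsies taken after progression are labeled
acquired resistance when time on the prior CDK4/6 inhibitor exceeded 6
months, intrinsic otherwise; missing durations give "unknown" rather than
a guess. Exome QC requires purity >= 0.08.

## Transcriptional scoring

**Normalization.** Upper-quartile: each sample is rescaled on the TPM
scale so its 75th percentile of nonzero expression equals 1000, then
re-logged. The target constant is arbitrary and documented as such — every
downstream consumer uses ranks or cohort-relative quantiles, both invariant
to it.

**Single-sample enrichment.** The weighted-ECDF form: rank genes by
expression descending, accumulate the in-set ECDF weighted by
`rank^0.75` against the uniform out-of-set ECDF, and sum the running
difference. The method family is standard; the exponent is not published
for this use, so 0.75 is the package default and a function argument.
Scores depend only on within-sample ranks, which the test suite pins down
with brute-force-oracle and rank-invariance properties.

**Normalized enrichment.** NES = ES / (max ES - min ES), per gene set,
over the analysis cohort plus reference jointly. The source analyses name
"normalized enrichment scores" without a formula; range normalization is
the simplest form that is linear in ES and stable for single-sample
scoring (no permutation null is available per sample). A zero range
yields all-zero NES with a warning.

**Reference quantiles.** High/low calls are relative to a
receptor-status-labeled reference expression cohort: high decile
(>= p90), high quartile (>= p75), low quartile (<= p25), low decile
(<= p10), ties inclusive — the value sitting exactly on p75 is "high".

**Subtype assignment.** Expression is rescaled by subtracting per-gene
medians of an ER-balanced reference subsample, then Spearman-correlated
with the five intrinsic-subtype centroids; the argmax wins, or Not
Classified below rho 0.10. The ER+ : ER- ratio of the original centroid
training cohort is not published; the default target is 0.64 ER-positive
and is configurable. Balancing samples without replacement in the limiting
class, with replacement (flagged) in the other when needed. The centroid
matrix shipped here is **synthetic**: built from block-level subtype shift
profiles over the 50 standard classifier genes, self-consistent with the
synthetic-cohort generator. It stands in for the published centroid
matrix, which is third-party data not redistributed with the package; to
classify real cohorts, pass the published 50 x 5 matrix to
`pam50_assign()`.

## The mechanism rule engine

The engine is data-driven: `inst/extdata/resistance_rules.tsv` maps
triggers (activating mutation, LOF/biallelic loss, high-grade
amplification, double activating mutation, ER loss by IHC, subtype,
signature or expression quantile category) to a pathway, the treatments
they bear on, and an evidence label. Known mechanisms (published
mechanistic evidence): activating *ESR1*, *ERBB2*, *FGFR1*, *AKT1*;
loss of *NF1*, *RB1*, *PTEN*; high-grade amplification of *FGFR1/2*,
*ERBB2*, *AURKA*; ER loss; Basal subtype. Plausible mechanisms:
*BRAF*, *MTOR*, double-*PIK3CA*; *IGF1R*/*INSR* amplification or high
expression; HER2-enriched subtype; high RTK signature or gene expression;
high or low ER activity. Transcriptomic "high" means high-quartile or
above; RTK activity is disjunctive across its signatures and receptor
genes. Where a feature plausibly affects both therapies it is recorded
against both — combination regimens rarely let the two be separated, a
limitation inherited from the clinical setting.

Per treatment, the verdict is the maximum evidence among applicable
features, so adding a feature can only promote. A patient is explained
when both treatments have at least one feature; the patient-level class is
known / known+plausible / plausible-only / unexplained.

## Clonal dynamics

Between a pre- and post-treatment pair, every alteration gets one status:
*acquired* (not detected pre — "not detected" is presence/absence, since
locus-level coverage is not modeled), *enriched* (subclonal to clonal, or
a strictly increased CNA class), *shared*, *lost* (clonal pre, absent
post), *pre-only* (subclonal pre, absent post). Acquired events keep their
post-sample clonality on the record; an acquired subclonal event is a
legitimate call. Between concurrent tumor and ctDNA samples, co-existing
lineages are called when both samples share truncal clonal alterations and
each carries a private clonal driver; a ctDNA mutation with CCF >= 0.6
counts as high-clonality for this purpose (ctDNA CCFs are deflated by
variable plasma tumor fraction; the threshold is configurable). Genes
activated privately in both samples by distinct events (mutation or
high-grade amplification) are flagged as convergent evolution. Threshold
logic replaces full phylogenetic clustering; multi-sample trees are out of
scope.

## Association statistics

AUC is computed from midranks, so tied pairs count one half, and
`AUC = U / (n1 n2)`. The one-sided Mann-Whitney p-value is the exact upper
tail of U under the permutation null, computed by the standard
partition-count recursion (exact up to 25 total samples; tie-broken or
larger inputs fall back to a flagged normal approximation). The two-sided
Fisher test uses the probability-mass convention. No multiple-testing
correction is applied anywhere in the primary outputs, matching the
exploratory design it mirrors; the signature screen emits a
Benjamini-Hochberg column as clearly-marked extra output. Trial efficacy:
CBR = (CR + PR + SD >= 24 weeks) / n, DCR with 12 weeks, percentages
half-up to one decimal; missing responses stay in the denominator and are
flagged.

## The synthetic-cohort generator

The generator exists because the real cohort is controlled-access; it
plants ground truth so every downstream stage is testable offline.

*Expression* is per-gene Gaussian in log2(TPM+1): baseline means drawn
once per configuration (N(6, 1.5), clamped to [0.5, 12]), receptor-class
shifts on the subtype marker blocks for the reference cohort (default
class counts 84 / 27 / 10 / 12 with the remainder unlabeled, 200 samples
total), subtype shifts plus driver-coupled signature shifts (default 2
log2 units; the p53 coupling is applied downward) for trial samples, and
i.i.d. noise (SD 0.5). Rank structure, which is all the scoring layer
consumes, survives upper-quartile normalization by construction; real TPM
dispersion, FFPE/frozen batch effects and read-level noise are not
emulated — passing tests demonstrate pipeline correctness on the planted
structure, not robustness to those artifacts.

*Genomics*: drivers are planted per a configurable frequency table
(defaults at landscape-like frequencies, e.g. *ESR1* 0.45), with canonical
protein changes, clonal CCFs drawn from [0.85, 1] and subclonal from
[0.1, 0.5] — straddling the 0.8 clonality threshold with margin.
Passenger mutations are Poisson (mean 30) over a synthetic gene pool so
knowledge-table lookups stay exact. Biallelic drivers get an LOH focal
segment; amplification drivers a CNAP 6.5 focal segment, reduced to GAIN
in paired pre-treatment bundles so the post state is enriched. Benefit
labels are drawn from a two-point model on the presence of an
mTOR-pathway driver (defaults 0.75 / 0.10). A configurable fraction of
patients receives a paired pre-CDK4/6i bundle (one driver deleted —
acquired — or demoted to subclonal — enriched); two patients by default
carry a divergent second lineage seen through a ctDNA bundle (truncal
*GATA3* frameshift, tumor-private *ESR1* activation, ctDNA-private *MTOR*
activation).

The truth manifest records planted alterations (all recoverable from the
emitted tables by exact gene + protein-change match), subtype, benefit
label, and the mechanism class implied by the planted genomic and clinical
features under the rule table. Transcriptomic features are validated
separately (signature-vs-driver AUC recovery, coupling monotonicity)
rather than folded into the manifest class: quantile categories flag
distribution tails by construction, so under any noise level some
driver-free samples legitimately land in quartile bins — equating planted
and reported classes through the transcriptomic route would test the
noise draw, not the engine. All randomness flows from a single config
seed through fixed per-stage substreams; identical configuration and seed
give byte-identical emitted files.

Default problem sizes used in the shipped tests — reference cohorts of
40–200 samples, trial cohorts of 5–100 patients, gene universes of
600–2000 — were chosen as the smallest sizes at which the planted effects
are unambiguous.

## Numerical and degenerate-input conventions

Boundaries are ties-inclusive where the class description says "at least"
(CNAP >= 3/6/9, CCF >= 0.8, purity >= 0.08, quantile categories) and
strict where it says "above" (GAIN > 1.5, acquired phenotype > 6 months).
All-zero expression samples, empty label classes, whole-universe gene
sets, empty contingency margins and zero-variance Welch inputs raise
errors or flagged p = 1 rather than silent answers. Serialized JSON uses
fixed precision so determinism is byte-level.

## Known limitations

* The clonality and ctDNA high-clonality thresholds are conventions, not
  published values; results near the boundaries should be read with that
  in mind.
* The shipped centroids and gene sets are synthetic stand-ins sized for
  validation; real analyses should supply the published centroid matrix
  and full MSigDB hallmark GMT.
* The exact Mann-Whitney tail assumes tie-free scores; tied data fall
  back to a flagged approximation.
* The rule table encodes the narrative feature list of the study it
  mirrors, not a per-patient figure grid; it is shipped as data precisely
  so it can be edited.
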