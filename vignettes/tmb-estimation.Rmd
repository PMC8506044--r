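---
title: "Estimating tumor mutation burden from tumor-only RNA-seq callsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor mutation burden from tumor-only RNA-seq callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatmb)
```

## The estimation problem

Tumor mutation burden is defined here as the number of called somatic
variants falling inside the analyzed exonic regions, divided by the size of
those regions in megabases. Substitutions and indels both count, and the
functional consequence of a variant is irrelevant to the count. Two design
consequences follow:

* **The denominator is always explicit.** `compute_tmb()` requires a region
  set and refuses an empty one. Hidden megabase constants are a major source
  of irreproducible TMB values between tools; here the BED file that defined
  the calling territory (or, for intersection-based analyses, the territory
  covered by both platforms) is a first-class input.
* **Filtering is the whole game.** A tumor-only RNA-seq callset contains,
  besides somatic variants: germline variants, formalin-fixation (FFPE)
  artifacts with a characteristic C>T (G>A) excess, and RNA-specific noise.
  An unfiltered count overestimates TMB by an order of magnitude; the
  package's job is removing the non-somatic part while keeping the somatic
  part, and quantifying how well that worked.

## Rule-based filtering

Three deterministic recipes cover the three callset flavors:

* **WES with matched normal** — keep `FILTER == PASS` only. The caller has
  already used the normal sample to remove germline variants, so the filter
  column is trustworthy.
* **WES tumor-only** — keep PASS records that additionally have ExAC ALL
  population frequency below 3.3e-5 and no dbSNP identifier. Population
  rarity and database absence substitute for the missing normal.
* **RNA-seq tumor-only** — keep records whose caller filter-label set is on
  a whitelist, with non-TCGA ExAC frequency below 3.3e-5 and no dbSNP
  identifier.

Numerical conventions, chosen once and applied everywhere:

* The frequency comparison is strict (`< 3.3e-5`); a variant at exactly the
  threshold is removed.
* An *absent* population frequency passes the rarity filter. A variant never
  observed in ExAC is rare by construction; treating absence as failure
  would discard nearly all somatic variants, which are precisely the alleles
  a population panel has not seen.
* dbSNP membership is true if either the VCF `ID` column carries an
  rs-identifier or the annotation field `avsnp150` is present — pipelines
  populate both channels (a dbSNP resource given to the caller, and a
  separate annotation step), and either is disqualifying.
* VCF `FILTER` values `.` and `PASS` both mean "empty label set": the VCF
  specification defines `.` as "filtering not applied", and a record without
  adverse labels should not be distinguishable from PASS downstream.

**The whitelist question.** In tumor-only mode a Mutect2-style caller flags
most true somatic variants as `germline_risk` (it has no normal sample to
prove otherwise), so the labels `germline_risk` and
`germline_risk;panel_of_normals` carry *candidate* variants, not rejects.
The default whitelist is therefore {∅ (PASS), {germline_risk},
{germline_risk, panel_of_normals}}. A stricter reading — keep only the
flagged records and drop PASS — is selectable by passing a whitelist without
the empty set to `filter_config()`; the package implements both because the
two interpretations cannot be distinguished from the method description
alone, and the choice is surfaced rather than guessed.

## Multiallelic sites

Tri- and higher-allelic sites are excluded at ingestion and counted, both
when a record lists several ALT alleles and when a caller has decomposed the
site into separate biallelic lines sharing (chrom, pos, ref). The exclusion
is site-level by intent: a site with evidence for two alternate alleles in a
tumor-only callset is far more likely to be a mapping or fixation artifact
than two co-occurring somatic events, and downstream feature semantics
(allele fraction, strand counts) are only well defined for biallelic
records.

## The signal/noise classifier

Rule filters cannot remove artifacts that carry benign filter labels and no
database annotation. The machine-learned filter targets exactly that
residue. Training data comes from samples where both platforms are
available: RNA-seq variants (pooled across training samples, unfiltered) are
labeled **signal** if a variant at the same genomic coordinate exists in
that sample's rule-filtered WES callset, **noise** otherwise. Labeling is
coordinate-based because the gold standard asserts "something somatic is
here", not that both callers represent the allele identically; the stricter
chrom/pos/ref/alt key is used for the `isec` upper-bound analysis, and both
are exposed in `label_by_wes()`. For pooled callsets each variant is matched
only against its own sample's WES reference — cross-sample matching would
label one patient's variants with another patient's genome.

Features (31 by default, `feature_registry()`):

* 23 caller fields taken directly from the VCF: TLOD, ECNT, POPAF, GERMQ,
  SEQQ, STRANDQ, CONTQ, ROQ, MPOS, MBQ and MMQ and MFRL as ref/alt pairs,
  `SA_MAP_AF_1`/`SA_MAP_AF_2` (maximum-likelihood allele fraction under a
  reverse-strand-artifact model and under no artifact), AD ref/alt, DP, AF,
  and the alt-strand read counts F1R2/F2R1. Different caller versions emit
  different subsets, so the registry is configurable; registered features
  missing from a dialect are all-NA columns. (Published feature lists for
  this procedure vary between 31 and 32 names in different places; the
  default registry fixes 31 and the registry hash guards train/score
  consistency.)
* 1 annotation feature: the non-TCGA ExAC population frequency.
* 7 engineered features from REF/ALT/AD: insertion and deletion flags
  (by length comparison), strand-collapsed C>T-transition and
  C>A-transversion flags (defined only for 1-bp alleles; longer alleles get
  0 for both, since substitution typing is meaningless for indels), total
  depth (AD ref + alt), and the literal REF/ALT string lengths.

Missing values stay missing: gradient-boosted trees route NA natively, and
imputation would inject information the data does not contain. A caller
field that is absent from a record is evidence in itself (e.g. strand
quality is only emitted when computable).

Training (`train_noise_classifier()`) is a randomized search over nine
hyperparameters — learning rate, number of estimators, min child weight,
gamma, subsample, colsample_bytree, max depth, reg alpha, reg lambda — with
five-fold cross-validation scored by ROC AUC. Defaults that were open
choices:

* **Stratified folds.** Signal prevalence in pooled callsets is typically
  below 1%; unstratified folds can produce single-class validation sets, so
  folds are stratified by class (configurable off).
* **Search budget 50 draws** by default, with the widest ranges on learning
  rate (log-uniform over 0.005–0.5) and estimator count (50–400), the two
  most influential parameters. The examples and tests in this package use
  smaller budgets (2–6 draws, 30–80 trees) because the synthetic fixtures
  are low-dimensional and saturate early; the budget is a `search_config()`
  argument, not a constant.
* **Classification cutoff 0.5** on the predicted signal probability, the
  neutral default for a probabilistic output; `apply_ml_filter()` exposes
  it, and the retained set is non-increasing in the cutoff.
* **No class re-weighting** by default; `scale_pos_weight` is exposed for
  users who prefer recall over precision at the default cutoff.

Everything is single-threaded and seeded (the booster's internal RNG is fed
from the R RNG stream), so a (data, config, seed) triple reproduces
bit-identical predictions. The positive class in confusion matrices is
signal: TP = labeled signal, predicted signal.

## Concordance evaluation

`build_concordance_report()` always takes gold high/low labels from the WES
side and uses raw RNA-seq TMB as the ranking score. AUC is computed in the
rank (Mann–Whitney) formulation with ties counted one half, which is exactly
"probability a random positive outranks a random negative"; the test suite
checks it against exhaustive pair enumeration. Correlations are two-sided
Pearson and Spearman (mid-ranks for ties, asymptotic p-values); no
multiple-testing correction is applied because the report makes no multiple
claims. Thresholds with an empty class report NA rather than a fabricated
AUC; constant TMB vectors report NA correlations with a warning.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates paired tumor-only RNA-seq and WES callsets
with a truth table, under study conditions fixed once in
`cohort_sim_config()`:

* true TMB per sample ~ log-normal, median 5 Mut/Mb, sdlog 1 (≈24% of
  samples at ≥10 Mut/Mb, matching the high-TMB fraction typical of mixed
  solid-tumor cohorts); the realized truth is the Poisson draw divided by
  the region size, exactly;
* regions: 25 intervals of 40 kb (1 Mb total) spread across chromosomes — a
  desk-scale stand-in for an exome, keeping per-sample variant counts in the
  tens;
* germline: 50/Mb, ExAC frequency 10^U(−3, −0.3) (always above the rarity
  threshold), 95% dbSNP-tagged; emitted in WES (flagged non-PASS in matched
  mode, PASS with annotations in tumor-only mode) and in RNA-seq subject to
  detection;
* FFPE artifacts 25/Mb with 80% C>T (G>A), RNA noise 25/Mb, both RNA-only;
* detection: each variant has expression ~ Exp(1); detection probability is
  `1 − exp(−(reads/3e7)·expr)`, giving mean detection ≈0.27/0.43/0.69 at
  11M/23M/68M mean gene-mapped reads — the three depth regimes of interest;
* class-conditional caller fields: TLOD log-normal located at 30 for real
  variants vs 8 for artifacts (sd 0.8, heavily overlapping), lower median
  base quality and read-position for artifacts, strand-biased alt reads and
  artifact-consistent `SA_MAP_AF_1` for artifacts. The overlap is
  deliberate: the classifier's advantage over rules should be learnable,
  not trivial.

Depth affects *only* detection and read-depth fields. All truth-level draws
happen before any depth-dependent draw, so `depth_sweep()` cohorts at
different depths share truth tables and WES callsets variant for variant,
and shared detection uniforms make detection nested in depth (anything seen
at 11M is seen at 68M). This isolates the coverage effect from cohort
resampling noise.

What passing tests on this generator do **not** show: real FFPE artifact
spectra are sequence-context dependent (CpG enrichment), RNA editing
(A-to-I) mimics true variation systematically rather than uniformly,
allele-specific expression biases detection toward expressed haplotypes,
and real exomes are 30× larger with correlated gene expression. Synthetic
results validate the machinery and the qualitative depth dependence, not
clinical performance.

## Problem sizes and runtime choices

The bundled checks use 8–40 sample cohorts over 1 Mb regions (hundreds to a
few thousand pooled variants), search budgets of 2–6 draws, and 10 replicate
seeds for the ML-vs-rule and depth-sweep comparisons. These sizes give
stable qualitative conclusions — the ML filter recovers true TMB at least as
well as rules in ≥8/10 replicates, and mean AUC at the 10 Mut/Mb threshold
is higher at 68M than at 11M reads — while keeping a full run in minutes on
one CPU.

## Known limitations

* The 23-name caller feature set is a reconstruction of standard
  Mutect2-dialect output; a different caller version needs a custom registry
  (supported, but the default is not universal).
* Indel handling assumes the caller left-aligned alleles; no re-normalization
  is attempted, so representation differences between platforms can defeat
  full-key matching (coordinate matching, the labeling default, is robust to
  this).
* The probability cutoff of 0.5 is not calibrated; on severely imbalanced
  training pools the classifier ranks well but shifts probabilities low, and
  count-based TMB in `ml` mode is sensitive to that shift. Ranking metrics
  (correlation, AUC) are robust; absolute `ml`-mode TMB values should be
  interpreted with the cutoff in mind.
* Very small cohorts (≲15 samples) can leave a threshold class empty or a
  TMB vector constant; the report degrades to NA with warnings rather than
  inventing numbers.
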