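---
title: "Classifying microsatellite instability from somatic mutational load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microsatellite instability from somatic mutational load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiclass)
```

## The problem

Microsatellites are tandem DNA repeats with unit lengths of a few base
pairs. When the mismatch-repair (MMR) machinery is lost — through mutation
or silencing of *MLH1*, *MSH2*, *MSH3*, *MSH6*, *PMS2* and relatives —
replication slippage at these loci goes uncorrected and tumors accumulate
length polymorphisms: microsatellite instability (MSI). MSI-high (MSI-H)
status matters clinically (prognosis, immunotherapy response), but the
reference assay, MSI-PCR on a five-locus Bethesda panel, is laborious.

MMR-deficient tumors also carry a characteristically elevated somatic
mutational load, visible directly in the mutation annotation format (MAF)
files that routine paired tumor–normal exome pipelines already produce.
`msiclass` exploits this: it summarizes a MAF into 22 per-megabase
mutational-load features and classifies each tumor as MSS (microsatellite
stable, the negative class, which absorbs MSI-low) or MSI-H (positive)
with a standardize + RBF-kernel support vector machine. Tumor type is
deliberately *not* a feature, so one model serves across tumor types.

## The feature panel

Every feature is a count of qualifying mutation records divided by the
captured exome length in megabases (the capture size), so cohorts
sequenced with different capture kits are comparable. Nine features come
from `Variant_Type` and repeat overlap:

| feature | definition |
|---|---|
| `SNP`, `INDEL`, `TOTAL` | per-Mb counts of single-nucleotide variants, micro-indels (`INS` + `DEL`), and all records |
| `SNP_R`, `INDEL_R`, `TOTAL_R` | the same, restricted to mutations overlapping a simple-sequence repeat |
| `RATIO_SNP`, `RATIO_INDEL`, `RATIO_TOTAL` | in-repeat count over overall count (dimensionless; defined as 0 when the denominator is 0, so downstream scaling never sees a non-finite value) |

DNP/TNP/ONP substitutions count toward `TOTAL` but not `SNP` or `INDEL`:
`SNP` literally means single-nucleotide, and the conservative reading
keeps the three families disjoint.

Thirteen more features count `Variant_Classification` categories per Mb —
`Frame_Shift_Del`, `Frame_Shift_Ins`, `In_Frame_Del`, `In_Frame_Ins`,
`Missense_Mutation`, `Nonsense_Mutation`, `Nonstop_Mutation`, `Silent`,
`Splice_Site`, `Translation_Start_Site`, `3'UTR`, `5'UTR`, `5'Flank` —
the translational/regulatory consequence of each mutation, which is what
separates clearly deleterious events (frameshifts above all) from neutral
ones. The classification list is configurable through `feature_spec()`;
only a core of the panel is fixed by the method's published description,
so the default thirteen are a documented reconstruction, the panel
carries a version tag, and trained models record which version they
assume (a mismatch at `load_model()` time is warned about and the model's
own panel wins).

## Repeat tagging

The repeat annotation is the UCSC `simpleRepeat` table. Only repeats with
unit length ≤ 5 bp are kept (`max_period = 5`): longer units cannot be
assayed reliably with the ~100 bp reads behind typical exome MAFs. UCSC's
0-based half-open coordinates are converted once, at the file boundary, to
the 1-based inclusive convention of MAF, and both readers strip `chr`
prefixes so the join between the two files can never miss on naming
dialect.

A mutation is "in repeats" if its closed interval shares *any* base with
any repeat interval — partial overlap counts, and an insertion (MAF
convention `End = Start + 1`, the two flanking bases) is in-repeat if
either flank is, since an insertion between two repeat bases sits inside
the repeat. Mutations on chromosomes absent from the track are flagged 0,
not rejected: tracks may legitimately omit alternate contigs. The
interval index is backed by per-chromosome `IRanges` structures and is
verified in the test suite against a brute-force linear scan on random
instances of 1000 mutations × 1000 intervals.

## The classifier

SVMs are sensitive to feature scale, so the model is a two-step pipeline:
per-feature standardization (mean 0, sd 1; a constant column keeps scale
1 so it standardizes to 0 rather than NaN) followed by a C-SVM with RBF
kernel $K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$. The decision
function is

$$ f(x) = \sum_i \alpha_i\, K(s_i, x) - \rho, $$

with support vectors $s_i$, dual coefficients $\alpha_i$ and intercept
$\rho$ oriented so that $f(x) > 0$ calls MSI-H. Scores come from these
stored arrays, not from an opaque fitted object, which buys two
properties: a persisted model (JSON metadata plus arrays, numeric values
as full-precision `%.17g` decimal strings) reproduces scores
bit-identically after reload, and the file is portable across
implementations. The inner SVM solve uses `e1071` (libsvm); the test
suite cross-checks our array-evaluated scores against libsvm's own
decision values to ~1e-15.

Hyperparameters $(C, \gamma)$ are tuned by exhaustive grid search with
class-stratified 10-fold cross-validation, selecting the largest mean
fold accuracy. The published description of the method fixes the search
procedure but not the grid, so the defaults are the community-standard
log-2 grids $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$, $\gamma \in
\{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$; ties break toward the smallest $C$,
then the smallest $\gamma$ — prefer the smoother model. The scaler is
refit inside every CV fold (the pipeline is what is cross-validated, so
no test-fold statistics leak into scaling). Classes are unweighted and
the decision threshold is the SVM's natural 0, with no probability
calibration; ROC and precision–recall curves are drawn from the raw
decision scores. The grid-search seed fixes fold assignment, making
training fully reproducible.

Cohorts are split 3:1 into training and test *within each tumor type*
(`stratified_split()`), with the per-stratum test count rounded half-up;
for the four-type design of 377/131/437/487 tumors this yields exactly
358 test tumors. Only this rounding rule is guaranteed — the exact
per-stratum mechanics of any particular historical split are not
reproducible without its seed.

## Evaluation

With MSI-H positive and MSS negative:
$Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Pre = TP/(TP+FP)$,
$Acc = (TP+TN)/n$, $G = \sqrt{Se \cdot Sp}$,
$F1 = 2 \cdot Pre \cdot Se/(Pre+Se)$. G-mean and F1 matter because the
cohorts are imbalanced (~1:4). A zero denominator raises an error naming
the metric — degenerate evaluation sets should fail loudly, not emit NaN.
Reports round to 3 decimal places; internal values keep full precision.

ROC curves sweep the distinct score values as thresholds with tied scores
grouped into a single threshold; the area is the trapezoidal sum, equal to
the probability that a random positive outscores a random negative with
ties counted one half (asserted against an $O(n^2)$ concordance oracle in
the tests). The precision–recall area is the step-wise average precision
$\sum_i (R_i - R_{i-1}) P_i$. Per-type evaluation runs the same machinery
within each tumor-type group, recording (rather than propagating) the
error for a group whose reference has a single class.

Per-feature class comparisons use two-sided Wilcoxon rank-sum tests
(`stats::wilcox.test`; exact for small untied samples, tie-corrected
normal approximation otherwise; a fully tied feature reports p = 1), with
no multiplicity correction. Feature importance comes from a seeded
`randomForest` fit (500 trees, $\sqrt{p}$ candidates per split,
Gini mean-decrease importances normalized to sum to 1); the forest ranks
features and is never the production classifier.

## The synthetic cohort generator

Real MAF cohorts cannot ship with the package, so `simulate_cohort()`
generates them. Design choices, and what they do and do not emulate:

* **Counts.** Per tumor and mutation family (SNV, micro-indel, DNP/TNP),
  event counts are negative-binomial with mean `rate × capture_mb` and
  dispersion `size = 3` — right-skewed marginals like real per-Mb load
  distributions. The distribution family is a simulation choice; nothing
  in the method depends on it.
* **Rates.** Defaults: MSS tumors average 2 SNVs, 0.2 micro-indels and
  0.05 multi-nucleotide substitutions per Mb with 6%/30%/6% of them in
  repeats; MSI-H tumors 12/3/0.3 per Mb with 10%/65%/10% in repeats and a
  higher frameshift share among indels (50% + 30% vs 40% + 25%). These
  are round numbers in the range reported for exome cohorts of stable vs
  MMR-deficient tumors, fixed once; under them every one of the 22
  features is elevated in MSI-H, and at 200 tumors per class every
  feature separates at rank-sum p < 0.01 (asserted in the tests).
* **Placement.** In-repeat events start inside a simulated repeat
  interval; out-of-repeat events are placed entirely within repeat-free
  sequence. The generator's per-event membership is therefore exactly
  what `tag_in_repeats()` recovers — asserted record-for-record — so the
  tagging path is testable without any reference genome. The synthetic
  genome is small (2 chromosomes × 10 Mb, 5% repeat density, unit
  lengths 1–5) so full-pipeline tests run in seconds.
* **Closed-form expectations.** The generator returns expected feature
  values per tumor: count features equal their rates; ratio features
  equal the in-repeat probability corrected for the negative-binomial
  zero mass, with a second-order delta-method correction for
  `RATIO_TOTAL` (a ratio of sums with random type weights). The test
  suite checks empirical means at 1000 tumors per class against these
  within 5% (plus three Monte-Carlo standard errors, which matters only
  for features with under ~0.1 events per Mb).
* **The four-type design.** `cohort_spec_tcga_like()` fixes the
  multi-stratum study conditions: 377/131/437/487 tumors of four types at
  44/44/50/44 Mb capture, per-type MSI-H prevalence 15%/3%/22%/30%
  (~21% overall). A small fraction of tumors is drawn with the *opposite*
  class's load profile while keeping its nominal label: 10% of
  endometrial and 4% of stomach MSI-H tumors are low-load (assay-positive
  tumors whose MMR system is effectively intact), and 1.2% of endometrial
  MSS tumors are high-load. This mirrors the discordance structure of
  real pan-tumor cohorts, where nearly all assay/classifier disagreements
  occur in endometrial and stomach tumors while colorectal tumors
  separate cleanly — and it is the sole reason synthetic performance sits
  near, not at, 100%.
* **Not emulated.** Mutational signatures, trinucleotide context,
  positional clustering, locus-specific repeat instability, sample
  contamination, caller artifacts. Passing tests on synthetic cohorts
  demonstrate that the pipeline's mechanics are correct and that the
  classifier recovers a class structure of this shape; they say nothing
  about performance on any particular real cohort, which depends on
  capture kits, callers and assay quality.

The effect-size knob of `cohort_spec()` interpolates the MSI-H profile
toward MSS (geometric interpolation for rates, linear for proportions);
held-out accuracy is non-decreasing in it, which the tests check at three
effect levels over five seeds each.

## Problem sizes used in tests and the acceptance script

End-to-end runs use the full 1432-tumor synthetic four-type cohort
(~320k mutation records), a compact hyperparameter grid
($C \in 2^{\{0,2,4,6\}}$, $\gamma \in 2^{\{-9,-7,-5,-3\}}$ — the default
grids' neighborhood of the optimum for standardized features) with
10-fold CV, and 10 independent split/training seeds; smaller unit tests
use cohorts of 40–200 tumors per class with a 2–4 point grid. These sizes
keep a full run in tens of seconds while leaving the selection procedure
intact.

## Known limitations

* The 13-category classification panel is a reconstruction; analyses that
  depend on the exact historical panel should configure `feature_spec()`
  explicitly and keep the version tag with their models.
* Tumor barcodes are used exactly as they appear in the MAF; any
  truncation needed to match clinical tables (e.g. trimming aliquot
  suffixes) is the caller's responsibility.
* The classifier is binary by design: MSI-L is folded into MSS on input,
  following the observation that MSI-L tumors carry an MSI burden
  indistinguishable from MSS. No three-class output is offered.
* Non-exonic classification categories (`Intron`, `3'Flank`, `RNA`,
  `IGR`) are parsed but not in the default panel; exome capture makes
  them rare and unstable as per-Mb rates.
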