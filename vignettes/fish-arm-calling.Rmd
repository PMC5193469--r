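---
title: "Calling chromosome-arm status from interphase FISH spot counts"
author: "FISHcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromosome-arm status from interphase FISH spot counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FISHcall)
```

## The problem

Dual-colour interphase FISH is the workhorse assay for chromosome-arm
copy-number status in diffuse gliomas: a red probe marks the target arm
(1p36.32, 9p21.3, 10q23.31 or 19q13.33) and a green probe the opposite arm
of the same chromosome, which acts as an internal copy-number reference.
Automated spot counting yields hundreds to >1,000 nuclei per slide, each
reduced to a pair of integer counts (red, green). Two nuisance processes
corrupt these counts: 5-micron sections truncate nuclei, so true spots drop
out, and hybridisation artifacts add spurious spots. The calling problem is
to go from noisy per-nucleus count pairs to a tumour-level status — deleted,
imbalanced (relative gain / polysomy) or normal — for each arm, robustly
enough to support the WHO-2016 integrated diagnosis, where 1p/19q
codeletion plus IDH mutation defines oligodendroglioma and every other
configuration is astrocytic.

## Per-nucleus classification

Each (red, green) pair maps deterministically to one of five categories
(`classifyNuclei()`):

* `(2, 2)` is normal;
* a red/green ratio at or below 0.5, with at least one red and two green
  spots, is a target-arm deletion;
* a ratio above 0.5 with a maximum count of at least 3 is
  polysomy/imbalance (copy-number increase without clean relative loss);
* `(1, 1)` is whole-chromosome loss (monosomy) — but only for chromosomes
  9 and 10, where loss of the control arm (9q, 10p) is a recognised event;
  on chromosomes 1 and 19 the same pattern is uninterpretable;
* everything else — no green signal, complete red dropout `(0, k)`,
  `(2, 1)`, `(1, 0)` — is uninformative.

Three interpretation choices deserve comment, since the category taxonomy
is where section-truncation physics meets the calling rules. First, the
`n >= 3` condition in the imbalance rule is read as
`max(red, green) >= 3`: imbalance means an increased copy number of red
and green signal, so `(2, 1)` is an artifact pattern, not imbalance.
Second, nuclei with zero red spots are uninformative rather than deleted:
complete dropout of a channel is far more plausibly truncation than
homozygous-style loss, and counting `(0, k)` as deletion would inflate the
deleted fraction of normal tissue. Third, uninformative nuclei are excluded
from every percentage denominator; all sample-level fractions are over
*analyzable* nuclei only.

## Tumour-level calling

`summarizeSample()` tallies the categories; `callArmStatus()` applies
percentage cutoffs in a fixed decision order:

1. if the imbalanced percentage exceeds the imbalance cutoff *I*, the
   sample is IMBALANCED — independently of its deletion status;
2. otherwise, if the deleted percentage (clean deletions plus, on
   chromosomes 9/10, the 1R/1G rate) strictly exceeds the deletion cutoff
   *D*, the sample is DELETED;
3. otherwise, if deleted + imbalanced together reach *D* (a mixed pattern
   without a clean majority clone), the sample is IMBALANCED;
4. otherwise NORMAL.

The inequality strictness follows the calling convention exactly: the
deletion rule and the imbalance override are strict (`>`), the mixed-sum
rule and the monosomy control-arm rule are inclusive (`>=`). On
chromosomes 9 and 10, a 1R/1G rate at or above *D* additionally flags the
control arm (9q/10p) as deleted — this is how a whole-chromosome-9 loss is
reported: 9p DELETED plus a 9q control-arm flag, not two separate deleted
arms.

Default cutoffs (`defaultCutoffs()`) are the routine values: *D* = 55%,
*I* = 20% for 1p and 19q; *D* = 30%, *I* = 40% for 9p; *D* = 25%,
*I* = 55% for 10q. The 9p/10q values derive from non-neoplastic brain
controls via mean + 3 SD.

```{r}
s <- summarizeSample("chr9", rep(c(1, 1, 2), c(45, 35, 20)),
                     rep(c(2, 1, 2), c(45, 35, 20)))
callArmStatus(s, defaultCutoffs())
```

### Calibration

`calibrateCutoffs()` reproduces the mean + 3 SD recipe: per chromosome,
*D* is the mean plus three standard deviations of the deleted-nucleus
percentages across control samples, and *I* likewise for the imbalanced
percentages. Two conventions had to be fixed that the recipe leaves open:
the SD is the sample (n − 1) standard deviation — the standard choice for
a five-sample reference series — and cutoffs are clamped below at 5% so
that noiseless controls cannot produce a degenerate near-zero cutoff.

### Quality control

A call is flagged unreliable when fewer than 50 analyzable cells were
scored (the reported failure mode of automated analysis on weak slides) or
when more than half the nuclei are uninformative. QC failure does not
suppress the call — it marks it, mirroring practice where a flagged slide
goes to secondary manual counting.

## The synthetic-data generator

Because no per-nucleus data are published for this assay family, the
package carries a generative model used by all stochastic validation:

* a tumour is a **clonal mixture**: each nucleus draws a clone (true
  target/control copy numbers) by mixture fraction — e.g. a deleted tumour
  is 85% cells of karyotype (1, 2) plus diploid admixture;
* detection is **lossy**: each true copy is seen with probability
  `pDetect`, a seen spot is double-counted with probability `pSplit`
  (signal splitting), and each channel gains Poisson background spots with
  mean `lambdaBackground`. Expected observed spots per channel are
  `pDetect * (1 + pSplit) * copies + lambdaBackground`.

Defaults: `pDetect` is probe-specific (0.90 for 1p/19q, 0.91 for 9p, 0.93
for 10q), `lambdaBackground` = 0.01, `pSplit` = 0.005, and control slides
add a slide-to-slide jitter on `pDetect` (SD 0.015) reflecting
hybridisation variability between specimens. These values are assumptions
— no noise parameters for control tissue are published — chosen once under
two constraints: (a) mean + 3 SD calibration on five simulated diploid
controls of 400 nuclei lands near the published 9p/10q deletion cutoffs of
30% and 25% (a diploid sample then shows ~19% and ~15% apparently deleted
nuclei, almost entirely from single-spot dropout), and (b) a diploid
sample's deleted + imbalanced sum stays safely below those cutoffs, so
normal tissue is called NORMAL — a property the calling workflow
presupposes. Dropout is independent per spot; correlated truncation
(both spots of one homologue lost together) is out of scope.

`simulateCohort()` adds the cohort layer: per diagnostic group (OII, OIII,
AII, AIII, GBM), probabilities over true arm states and marker statuses
equal to the empirical per-group frequencies of the packaged 33-case
series, plus exponential survival with hazard equal to the reciprocal of
the group mean survival (108, 86, 156, 81, 19 months) and independent
exponential censoring tuned to ~21% censored (Weibull death times are
available via the `shape` argument). Exponential survival is chosen for
analytic tractability — recovery tests can compare KM medians against
ln 2/λ in closed form.

What the generator does *not* emulate: spatial structure and segmentation
errors (spot counting is taken as given), correlated dropout, focal or
homozygous deletions, amplification categories beyond polysomy, and
non-proportional hazards. Passing simulation tests therefore validates the
calling and statistical machinery under the stated noise model, not the
upstream image analysis.

## The packaged reference cohort

`cohortFixture()` returns a frozen 33-case series (13 OII, 10 OIII, 3 AII,
3 AIII, 4 GBM) whose per-group marginal counts — molecular status per arm,
IHC (IDH1-R132H, ATRX, INA), MVP type, calcifications, mitoses, Ki-67 —
are all fixed. Joint assignments beyond the recorded constraints are
arbitrary but frozen and checksum-verified on load. The documented
construction choices: the two whole-chromosome-9 OIII cases are among the
seven 9p-deleted OIII; the single 1p-deleted AII carries the
19q-imbalanced status its column margins require; the single
IDH1-IHC-negative OII carries an IDH2 sequencing override; the GBM with
1p deletion is also one of the two 10q-deleted GBMs. Mitotic counts per
case were chosen to match each group's printed mean *and* median under
round-half-up formatting.

The paired-call fixtures (`concordanceFixture()`) freeze a
manual-vs-automated disagreement pattern with the reported agreement
structure: chromosome 9 agrees in 25/33 cases (76%) and 25/31 (81%) after
excluding the two weak-signal cases; chromosome 10 in 23/33 (70%) and
22/28 (79%) after excluding five. The exact confusion matrices behind the
published kappas are not recoverable from agreement counts alone, so the
fixtures' kappas (0.63/0.71 and 0.43/0.57) are near, but not equal to, the
published 0.65/0.69 and 0.40/0.62; only the agreement percentages are
treated as reproduction targets.

## WHO-2016 rule engine

`integratedDiagnosis()` composes two rules. Lineage: oligodendroglioma iff
IDH-mutant *and* 1p and 19q both DELETED (an IDH2 sequencing result
overrides a negative IDH1-R132H immunostain); anything else is
astrocytic. Grade: oligodendrogliomas are III on glomeruloid MVP or
mitoses ≥ 6/10 HPF; astrocytomas are IV (GBM) on glomeruloid MVP or
necrosis, III on mitoses ≥ 2, else II. The mitotic thresholds are not
numeric in the WHO text; the defaults are the configuration under which
the engine reproduces the reference series' 13/10/3/3/4 regrouping, and
both are exposed in `gradingThresholds()`. The benign endocrinoid
(chicken-wire) vasculature is never treated as MVP. ATRX and INA are
carried through for reporting but never decisive.

## Statistics

Group comparisons use Pearson chi-square with Yates continuity correction
on 2×2 tables (`chiSquareTest()`); Yates is the convention under which the
9p OII-vs-OIII comparison [[0,13],[7,3]] yields p = 0.0016, printing as
0.002, where the uncorrected test gives ≈ 0.0003. Fisher's exact test is
available for sparse tables. Concordance uses unweighted Cohen's kappa
(`cohensKappa()`) with an explicit undefined-kappa path for degenerate
marginals, and interpretation bands (good: 0.6–0.8; high: > 0.8).
Deleted-arm counts (`deletionCountSummary()`) follow the
count-chromosome-9-once convention: a whole-chromosome-9 loss contributes
one deleted arm via 9p, with the 9q flag reported separately — the only
convention under which all six per-group mean cells (2 / 2.7 / 0.3 / 0.3 /
1.75 / 1.9) are internally consistent. Survival uses the survival package:
Kaplan-Meier product-limit curves (median reported as undefined, not
infinite, when the curve stays above 0.5), log-rank tests, and Cox
proportional-hazards fits with Breslow tie handling, a two-stage workflow
(`screenCovariates()` then `coxFit()`) mirroring univariate screening at
p < 0.05 before the multivariate model, and explicit flagging of monotone
likelihood (perfect separation) instead of silent estimates. Standard
dichotomizations (age 50, mitoses 5, Ki-67 12%, INA 10%, ATRX 10%) are in
`dichotomize()`.

Published cohort-level survival results (median OS tables, hazard ratios)
require patient-level data that are not public; the survival machinery is
therefore validated by simulation — type-I error of the log-rank test at
nominal 5%, power against a threefold hazard ratio, 95% CI coverage for a
true HR of 2, KM median recovery against the exponential closed form —
rather than by reproducing printed values.

## Numerical conventions and problem sizes

Report percentages round half-up to integers (`roundHalfUp()`), matching
clinical-table formatting (75.76 → 76); internal computation is full
precision. Validation problem sizes were chosen to keep the suite fast at
desk scale while leaving comfortable statistical margins: 500–600 nuclei
per simulated sample (within the reported 81–1,453 per-slide range), 200
replicates for call-recovery and Cox-coverage checks, 2,000 replicates for
the log-rank type-I error, and a 121-point exhaustive enumeration per
chromosome for the per-nucleus rules.

## Known limitations

The caller has no category for focal homozygous deletion (two-red-spot
loss) or high-level amplification; both collapse into the existing
taxonomy. The uninformative taxonomy is a stand-in for whatever per-cell
rejection the commercial counting software applies, which is not publicly
specified. The simulator's independence assumptions (per-spot dropout,
per-channel background) are convenient rather than measured; real
truncation is correlated within a nucleus. The grading thresholds are
calibrated to one 33-case series and should be re-examined before use on
other cohorts.
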