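---
title: "Measuring the test–retest reproducibility of lesion-detection CAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the test–retest reproducibility of lesion-detection CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprocad)
```

## The problem

A computer-aided detection (CAD) model for pulmonary nodules and masses is
usually judged by its detection performance on a single reading of each
image. In clinical use, however, the same patient is imaged repeatedly —
often within days, with no change in disease — and a model that flags a
lesion on Monday but not on Friday erodes trust regardless of its average
sensitivity. `reprocad` quantifies that *test–retest reproducibility* for
detectors that output bounding boxes with confidence scores, given paired
initial and follow-up exams of the same patients in which every lesion is
annotated in both exams and carries a shared identity.

The package evaluates agreement between the two readings of each pair; it
does not train or embed any detector. A deliberately simple
difference-of-Gaussians blob detector is included only so the full pipeline
can be exercised end to end on rendered toy images.

## The pipeline

**Hit criterion.** A detection counts as a hit on a lesion when the
intersection-over-union (IoU) of the two boxes *exceeds* 0.5. We read
"over" as a strict inequality; `strict = FALSE` switches to `>=` if a
different convention is needed. Boxes are axis-aligned, in continuous pixel
coordinates, origin top-left.

**Assignment.** Detections are matched one-to-one to lesions greedily in
order of decreasing confidence; each detection claims the unclaimed lesion
of highest IoU among those above the threshold. Ties in confidence are
broken by the higher best-available IoU and then by input order, so a rerun
on the same files reproduces the same assignment bit for bit. One-to-one
matching follows standard detection-evaluation practice; duplicate
detections of an already-claimed lesion count as false positives.

**FROC and operating points.** Sweeping the confidence threshold over every
distinct score yields the free-response ROC curve: lesion sensitivity
against average false positives (FP) per image. Reproducibility is then
read off at a fixed grid of FP budgets — 0.1, 0.2, 0.3, 0.4 and 0.5 average
FP per image by default. For each budget the operating threshold is the
smallest `tau` whose average FP stays within the budget (i.e. maximal
sensitivity subject to the budget); an unreachable budget silences the
detector (`tau = Inf`). The curve used for threshold selection is built
from the initial exams only, because ground truth in the motivating setting
was delineated on initial exams; `froc_source = "both"` is available.

**JAFROC figure of merit.** Localization performance is summarized by
\[
\mathrm{FOM} \;=\; \frac{1}{N_I N_L} \sum_{i=1}^{N_I} \sum_{l=1}^{N_L}
\psi(F_i,\; r_l),
\qquad
\psi(F, r) = \begin{cases} 1 & r > F \\ 1/2 & r = F \\ 0 & r < F, \end{cases}
\]
where \(r_l\) is the confidence of the detection that hit lesion \(l\)
(\(-\infty\) for a miss) and \(F_i\) the highest false-positive confidence
in image \(i\) (\(-\infty\) if none); a doubly-undetected pair scores 1/2.
Every image in this setting contains at least one lesion, so the variant
that uses the highest false positive of *every* image (rather than of
lesion-free images only) is the natural choice. The FOM depends on the
confidences only through their ordering — any strictly increasing
transform leaves it unchanged, which the test suite checks.

The 95% interval on the FOM is a percentile bootstrap over *patients*
(2000 resamples by default): the patient is the independent sampling unit,
and both exams of a drawn patient enter the resample together. A
leave-one-patient-out jackknife with a t-interval is available via
`method = "jackknife"`. Resamples that happen to carry no lesion are
redrawn. The reported interval is widened, if necessary, to bracket the
full-data point estimate, so the printed triple is always internally
consistent.

**Paired agreement.** At each operating threshold every lesion falls into
one cell of the paired confusion: detected in both exams (`a`), only in the
initial (`b`), only in the follow-up (`c`), or in neither (`d`). The two
agreement statistics are
\[
\mathrm{PPA} = 100\,\frac{2a}{2a+b+c}, \qquad
\mathrm{CPPA} = 100\,\frac{a}{a+b+c},
\]
with `d` never entering either — the cohort consists of patients whose
disease persists, so joint silence is not evidence of agreement worth
crediting. For any single confusion the two are algebraically linked,
`CPPA = 100 * PPA / (200 - PPA)`; the link does *not* survive averaging
over operating points, which is why a mean PPA and mean CPPA reported side
by side need not satisfy it. Per-operating-point values are aggregated as
the arithmetic mean and *population* standard deviation (divide by the
number of operating points): the five values are an exhaustive set of
descriptive readings, not a sample from a larger population. When a
detector produces no false positives at all, every budget selects the same
threshold and the spread collapses to exactly 0.00 — a behaviour one also
sees in published comparisons when operating points coincide.

**Counting unit.** `a`–`d` are counted per *lesion* by default: the natural
reading of "the same nodule was detected", and the one that uses all
annotated lesions (a validation set can easily hold more lesions than
pairs). `unit = "exam"` collapses each patient to a single unit that is
positive when at least one lesion is detected, for sites that prefer
exam-level agreement.

## The simulator

`simulate_paired_detections()` generates paired detector output with known
reproducibility structure. Per lesion, the two per-exam detection events
follow a **shared-draw mixture**: with probability `rho` both exams reuse a
single Bernoulli(`s`) draw, otherwise each exam draws independently. This
mechanism was chosen over a Gaussian-copula alternative because it makes
the target quantity available in closed form,
\[
E[\mathrm{PPA}] \to 100\,(\rho + (1-\rho)\,s),
\]
since \(P(a) = \rho s + (1-\rho)s^2\) and
\(P(b)+P(c) = 2(1-\rho)s(1-s)\); `expected_ppa()` and `expected_cppa()`
expose the closed forms, and the parameter-recovery suite checks the full
pipeline against them within three Monte-Carlo standard errors on a
\(s \in \{0.6, 0.8, 0.95\} \times \rho \in \{0, 0.5, 0.9\}\) grid.

Defaults describe the study conditions the package is modelled on: 121
exam pairs; lesion multiplicity `1 + Bernoulli(13/121)` (about one patient
in nine carries a second lesion); detector sensitivity 0.8, matching the
mid-grid sensitivities observed for convolutional detectors at the 0.2-FP
operating point; and one raw Poisson false positive per image, enough for
thresholding to realize every budget in the 0.1–0.5 grid. Between-exam
correlation has no published estimate; the default `rho = 0.5` sits
halfway between independent readings and a deterministic detector and is a
placeholder, not an estimate.

Three constructions make the simulator's latent events *exactly*
recoverable by the pipeline, which is what turns the closed form into a
testable oracle:

* **Jitter-safe true positives.** A detection box is a translated copy of
  its lesion box, each axis displaced by at most `box_jitter` (a fraction
  of the side length). A pure translation by fractions \(a, b\) of the two
  sides has IoU \(\frac{(1-a)(1-b)}{2-(1-a)(1-b)}\) with the original,
  which stays above 0.5 whenever `box_jitter` \(\le 0.18\); the
  configuration validator enforces that bound, so a true detection can
  never fail the hit criterion. The default is 0.12.
* **Disjoint lesions.** The (at most two) lesions of a pair are rejected
  until disjoint with a margin. Because the Jaccard distance \(1 -
  \mathrm{IoU}\) is a metric, a detection cannot have IoU above 0.5 with
  two disjoint boxes at once — so a true positive always claims its own
  lesion and greedy matching provably equals the exhaustive
  maximum-cardinality assignment on such instances (the oracle-equivalence
  suite exploits the same fact).
* **Clear false positives.** False-positive boxes are redrawn until their
  IoU with every lesion of the exam is at most 0.1, far below the hit
  criterion, so they can never steal a lesion.

Confidence scores default to Beta(6, 2) for true positives and Beta(2, 6)
for false positives — overlapping but well-separated, so the FROC curve has
usable operating points; only the ordering of scores matters downstream.

The rendered-image path (`render_pair_images()`, `toy_blob_detector()`,
`simulate_image_dataset()`) draws lesions as Gaussian bumps on noise, with
the follow-up re-rendered at jittered positions under inflated noise
(`followup_noise_factor`, default 1.5) to mimic the poorer acquisition
conditions typical of unscheduled follow-up radiographs. The detector is a
difference-of-Gaussians pyramid (geometric scale ladder, 3×3×3 local
maxima above a response floor, boxes of half-width \(2\sigma\) at the
detected scale, greedy non-maximum suppression at IoU 0.3, confidence a
saturating linear map of the response). None of this is anatomically
realistic: there are no ribs, no varying lesion conspicuity, no
registration error beyond translation. Passing the end-to-end suite
therefore demonstrates that the *evaluation machinery* is correct and
deterministic, not that any particular detector is reproducible on real
chest radiographs.

## Numerical and design choices

* IoU exactly at the threshold is a miss under the default strict
  inequality; the boundary case is pinned by a dedicated test.
* Detection input order is preserved within an exam through serialization
  (it is the final matching tie-break); exams and lesions are kept in a
  canonical C-locale order so that write-then-read is the identity and
  repeated writes are byte-identical.
* Thresholding is applied to a *fixed* assignment (matching once on all
  detections, then discarding low-confidence ones), not by re-matching per
  threshold; this keeps `tp` monotone in `tau` by construction.
* `threshold_at_fp()` returns `Inf` when no point meets the budget;
  downstream code treats it as a silenced detector, and an all-silent
  operating point leaves PPA/CPPA undefined (reported as `NA` with a
  warning rather than an arbitrary value; the JSON serialization of an
  infinite threshold is `null`).
* Agreement on zero detected lesions (`a = b = c = 0`) is an error by
  design, not 0 or 100.
* Simulated confidences are clamped to `[1e-12, 1]` so a permissive
  threshold of 0 retains every detection.

## Problem sizes

The shipped test suite runs the parameter-recovery grid at 5000 pairs per
cell, the oracle-equivalence suites at 500 random instances each, the FROC
property suite at 1000 instances, and the end-to-end image pipeline at 20
pairs of 256×256 images; the whole suite completes in about two minutes on
one core. These sizes were chosen so Monte-Carlo error is small relative
to the tolerances being checked; the simulator itself scales to much
larger cohorts.

## Limitations

* Lesion correspondence across the pair must be supplied as shared
  `lesion_id`s; the package does not register images or infer
  correspondence.
* The bootstrap/jackknife interval treats patients as exchangeable; it
  does not model reader or scanner effects.
* Between-method significance testing of FOM differences (DBM/OR-style
  reader-study models) is out of scope, as are kappa-type chance-corrected
  agreement statistics — PPA and CPPA are deliberately simple and
  prevalence-sensitive.
* The simulator's follow-up degradation model (translation jitter plus
  noise inflation) has no quantitative anchor in published data; treat its
  parameters as placeholders when interpreting end-to-end numbers.
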