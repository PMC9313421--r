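---
title: "Regional vascularity quantification and diagnostic evaluation of thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional vascularity quantification and diagnostic evaluation of thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrovasc)
```

## The problem

Grey-scale thyroid ultrasound stratifies nodules for biopsy through TIRADS
risk categories, but vascular architecture carries complementary signal:
malignant nodules tend towards central (intranodular) flow while benign
nodules tend towards peripheral flow. Colour Doppler still frames encode
flow as a pure-colour overlay on the greyscale B-mode image, so regional
flow burden can be quantified by counting colour pixels. `thyrovasc`
implements that quantification chain and the statistics used to judge its
diagnostic value, end to end:

1. partition a manually outlined nodule ROI into **central** and
   **peripheral** regions by an offsetting principle;
2. count colour pixels per region to form **vascularity indices** (VI) and
   their ratio, the **RVI**;
3. classify nodules by the RVI rule, by qualitative flow grades, by
   rule-based **EU TIRADS** categories, and by the TIRADS-AND-vascularity
   combination;
4. evaluate each classifier with exact binomial confidence intervals,
   single-operating-point AUROC, and the paired tests appropriate for
   classifiers measured on the same nodules.

Because clinical Doppler images are rarely shareable, the package carries a
synthetic-data module producing Doppler-like phantoms with *exact*
colour-pixel ground truth and simulated cohorts with the study's label
structure, so the whole pipeline is testable without any clinical data.

## Offset segmentation

The whole-nodule ROI (a binary mask) is split at an offset fraction
$f$: a pixel $p$ belongs to the central region iff

$$ d(p) \;\ge\; f \cdot \max_q d(q), $$

where $d(p)$ is the Euclidean distance from $p$ to the ROI boundary
(ROI pixels 4-adjacent to background; frame edges count as background).
The peripheral region is the remaining rim. The default $f = 0.22$ is the
value established as diagnostically optimal for thyroid nodules in the
protocol this package implements.

Design notes, where the geometry was genuinely open:

* **Offset basis.** Published descriptions of the offsetting principle do
  not pin down whether the offset is a fraction of an equivalent radius, of
  the local radius, or of the maximum inscribed distance. We threshold on
  the distance transform at a fraction of the maximum inscribed distance:
  it is well defined for arbitrary (including non-convex) shapes, reduces
  to the concentric-disk construction on a circle, and is a pure function
  of the mask. A `contour_scale` alternative (shrink towards the centroid
  by $1 - f$) is provided for sensitivity analysis.
* **Tie-breaks.** Pixels exactly at the threshold go to the central region
  ($\ge$, not $>$), so $f = 0$ maps the entire ROI to central; at $f = 1$
  the argmax set of $d$ remains central, so the central region is never
  empty.
* **Exactness.** The distance transform is the two-pass lower-envelope
  algorithm on squared distances, which is exact on integer grids; the test
  suite verifies pixel-for-pixel agreement with an exhaustive
  minimum-over-boundary-pixels oracle on masks up to 64×64.
* **Discretisation.** On a rasterised circle of radius 100 px at
  $f = 0.22$ the central area fraction comes out near (but, because
  boundary pixels sit *inside* the ROI at distance 0, roughly one percent
  below) the continuum value $(1-f)^2 = 0.6084$. Tests therefore assert
  oracle-exact geometry plus an absolute one-percentage-point band on the
  area fraction, not the continuum value itself.
* **Multi-component masks** are processed as a single region with a
  warning; the protocol excluded nodules that could not be clearly
  isolated.

## Vascularity indices

A pixel is a **colour pixel** iff $\max(R,G,B) - \min(R,G,B)$ exceeds the
chroma threshold (default 10 on the 0–255 scale). Doppler machines overlay
pure colour on greyscale, so genuine background has zero chroma; the
nonzero default absorbs mild compression noise. Anti-aliased overlay edges
are the one genuinely ambiguous zone; the threshold is the user's control
for them. Raising the threshold can only shrink the colour mask, so every
VI is non-increasing in it (a property the tests check).

For a region $R$, $\mathrm{VI}(R) = 100\,|C \cap R| / |R|$ with $C$ the
colour mask. Per protocol three replicate frames are read per nodule and
mode; regional VIs are averaged across replicates and the ratio is formed
from the means:

$$ \mathrm{RVI} = \frac{\overline{\mathrm{VI}}_\text{peripheral}}
                       {\overline{\mathrm{VI}}_\text{central}} $$

RVI > 1 denotes predominantly peripheral flow (suspicious for benignity),
RVI ≤ 1 predominantly central flow (suspicious for malignancy). We read the
protocol's "averages … then ratio analysis" as ratio-of-means rather than
mean-of-ratios; ratio-of-means is also the numerically stabler choice when
a replicate's central VI is near zero. Degenerate cases: zero mean central
VI with peripheral signal gives RVI = ∞ (benign-suspicious); both means
zero marks the record `non_vascular`, and such records are excluded from
evaluation with a logged count, mirroring the protocol's exclusion of
non-vascular nodules. Qualitative grades map I/II → benign-suspicious and
III/IV → malignant-suspicious.

## EU TIRADS rules and the combination

The rule-based categoriser assigns category 5 on any high-risk feature
(irregular margins, marked hypoechogenicity in a solid or mixed nodule,
taller-than-wide shape, microcalcifications), else 4 for mild
hypoechogenicity, else 2 for pure cysts and spongiform nodules, else 3.
Mixed cystic-solid nodules are categorised by their solid component, the
standard convention. The sole grey-scale assessment is positive at
category ≥ 5; the combined assessment lowers the cut-off to ≥ 4 and
predicts malignant only when **both** the TIRADS cut-off and the
vascularity suspicion are positive. The AND can only remove false
positives, so combined specificity is bounded below by each component's
and combined sensitivity bounded above — the direction of change the
clinical evaluation reports (specificity 50% → 84.4%, sensitivity
83.3% → 76.7% for the qualitative APDI combination).

## Diagnostic statistics

* **Confusion metrics.** SEN, SPEC, PPV, NPV from the matrix; FNR and FPR
  as complements. Binomial CIs are exact Clopper–Pearson from beta
  quantiles.
* **AUROC.** A single-threshold binary test has a two-segment ROC polygon
  whose trapezoidal area is $(\mathrm{SEN} + \mathrm{SPEC})/2$; that is the
  estimator reported here, and it reproduces every internally consistent
  AUROC cell of the evaluation tables. Its CI uses the Hanley–McNeil
  standard error (the source tables' CI method is unstated, so their
  printed AUROC CIs are not reproduction targets).
* **McNemar.** Default exact binomial form, appropriate for the small
  discordant counts at n = 94; the continuity-corrected chi-square form is
  available and follows the convention of dropping the correction under
  exact symmetry (b = c), so a perfectly symmetric table gives statistic 0.
* **Cochran's Q** across ≥ 3 modes, reducing to the uncorrected McNemar
  chi-square at k = 2.
* **AUROC z-test** with Hanley–McNeil standard errors, unpaired. Whether
  the original analysis accounted for the pairing of AUROCs measured on the
  same nodules is unstated; the unpaired form is implemented and so
  labelled (it is conservative for positively correlated estimates).
* **Cohen's kappa** (unweighted) with proportion agreement for intra-rater
  grading reliability; **paired t-tests** for mean regional VIs between
  paired modes (first minus second); **Pearson chi-square** (no continuity
  correction) for classification tables, with a one-sample variant against
  $p_0 = 0.5$ for "RVI > 1 within benign nodules".
* Percentages are reported to 1 decimal and AUROC to 2, rounding half away
  from zero, matching the tables; no multiple-testing adjustment is
  applied, mirroring the protocol.

Reconstruction: because `tp = round(SEN·n_pos/100)` and
`tn = round(SPEC·n_neg/100)` are integers, every reported table column is
recomputable from its printed SEN/SPEC and the class sizes.
`check_reported_consistency()` does this for all 22 columns. Nineteen
reproduce their printed PPV, NPV and AUROC exactly at the tables' rounding.
Three cells do not follow from their own printed SEN/SPEC: two AUROCs
(sole grey-scale and qualitative CFI, both in the equivocal cohort, printed
0.62/0.79 vs derived 0.64/0.78) and the quantitative combination's
all-nodule column, whose printed sensitivity 58.1% implies a denominator of
31 rather than 30. These are flagged, not "corrected".

## The synthetic-data module

**Phantoms.** A phantom is a greyscale background (flat, or multiplicative
speckle on a smooth base, clipped to 8-bit), a circle/ellipse/blob ROI, and
colour disks (radius 1–3 px, shrinking to single pixels near the target)
painted at uniformly sampled centres strictly inside each target region
until the requested coverage is met — so the achieved per-region
colour-pixel counts are recorded exactly, and the spec's chroma rule
recovers precisely the painted set. The palette mimics directional
(red/blue) or power (orange) maps with chroma far above threshold.
Identical spec and seed give bit-identical images. What phantoms do *not*
emulate: acoustic physics, colour-gain artefacts, aliasing, flash
artefacts, anti-aliased overlay edges, and operator variability — so
passing recovery tests validates the counting chain, not robustness to
real acquisition artefacts.

**Cohorts.** A simulated cohort realises the study structure exactly: 94
nodules (30 malignant, 64 benign), 40 cytologically equivocal (9 malignant,
31 benign), four Doppler modes (CFI, ACFI, PDI, APDI), three replicate VI
pairs per nodule and mode. Two per-mode operating-point maps drive the
indicators — qualitative grading and RVI classification — defaulting to the
all-nodule sensitivities/specificities reported for each family (e.g. APDI:
83.3%/81.3% qualitative, 66.7%/73.4% RVI). For a malignant nodule the
malignancy-suspicious indicator is Bernoulli(SEN); for a benign one,
Bernoulli(1 − SPEC); indicators are independent across modes given truth
unless a shared-latent correlation is requested. The equivocal flag is
assigned independently of the indicators given truth. Replicate VIs are the
nodule mean ± Gaussian jitter (default sd 3 VI points, a plausible
frame-to-frame repeatability for a stable scan), truncated to [0, 100];
nodule means are drawn with the dominant region's VI uniform on 25–65 and a
dominance ratio uniform on 0.45–0.90, consistent with the reported mean
regional VIs (roughly 26–57 across modes and regions). Where jitter flips a
replicate-mean RVI across the threshold, the regional columns are swapped
so the realised indicator matches the drawn one. TIRADS categories are
drawn per truth class — malignant (2,3,4,5) = (.033,.067,.067,.833), benign
(.20,.20,.10,.50) — fixing the sole-EU operating point at the reported
SEN 83.3%/SPEC 50.0% (cut-off ≥ 5); the category-4 mass is not identifiable
from the reported tables and was fixed once at a plausible value. Each
category is then back-filled with a canonical grey-scale feature record the
rule engine maps to that category, so the TIRADS module is exercised on
every simulated nodule.

## Numerical and scale choices

* All randomness flows from one master seed per spec; substream seeds are
  derived deterministically, and generators restore the caller's RNG state.
* Unit-test geometry uses masks up to 64×64 (where the exhaustive oracle is
  cheap); phantom-recovery tests use 96–220 px frames; simulated-cohort
  property tests use n = 94 for structure and n = 100,000 for
  operating-point recovery (binomial standard error ≈ 0.2 points, well
  inside the ±1-point band). The default suite runs in well under a minute
  on one core.
* PNG is used for fixtures; the original protocol's export format is not
  recoverable from its description (screen captures in TIFF were
  processed offline), and PNG is lossless, ubiquitous and
  single-channel-capable for masks.

## Known limitations

* The offset geometry is one defensible reading of the offsetting
  principle, not a byte-level reimplementation of the original MATLAB tool.
* Qualitative grading is a human act; the package only encodes grades and
  simulates raters at fixed operating points.
* The AUROC z-test is unpaired; paired alternatives (e.g. DeLong for
  score-based tests) do not apply to single-threshold binary tests.
* Simulated cohorts draw indicators at fixed operating points; they do not
  model nodule-level difficulty, reader drift, or correlation between
  TIRADS features and vascularity beyond the truth label.
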