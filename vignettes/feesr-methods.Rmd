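---
title: "Quantifying pharyngeal residue and airway invasion from tracked FEES frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pharyngeal residue and airway invasion from tracked FEES frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feesr)
```

## The problem

Fiberoptic endoscopic evaluation of swallowing (FEES) produces dark,
unevenly lit video of the laryngopharynx. Two families of findings drive
clinical decisions: pooled **pharyngeal residue** in the valleculae and
pyriform sinuses, graded on the five-level Yale Pharyngeal Residue
Severity Rating Scale (YPR-SRS: absence, trace, mild, moderate, severe),
and **airway invasion** — penetration (material entering the laryngeal
vestibule) and aspiration (material passing below the vocal folds). Both
are conventionally read by eye and are sensitive to lighting and
examiner experience.

`feesr` implements the computational half of a semi-automated workflow.
Upstream, a markerless pose-estimation network (DeepLabCut-style) tracks
three laryngopharyngeal structures — epiglottis, arytenoids and vocal
folds — and emits per-frame coordinates with a per-point likelihood. The
package consumes that CSV together with the raw frames and the
clinician-selected swallow intervals, and automates everything after:
frame quality control, image enhancement, region-of-interest (ROI)
construction, residue quantification, severity grading, invasion
screening and diagnostic-agreement statistics.

## Frame selection and quality control

Tracking likelihood is treated as the accuracy of each landmark. A frame
is *adequate* when every tracked point reaches the likelihood threshold
(default 0.70). The threshold aggregation is configurable
(`adequacy_method = "mean"`) because per-point and mean-over-point
readings of a "70% accuracy" criterion are both defensible; the
all-points default is the conservative choice. A video is excluded when
inadequate frames exceed 50% of all frames — strictly: exactly half
still passes.

During the pharyngeal swallow the constricting pharynx floods the lens
(**whiteout**), so scoring frames are chosen immediately before and
after it. Frame *i* covers time `[i/fps, (i+1)/fps)`; the whiteout frame
is `floor(t_whiteout * fps)` and is excluded from both search windows.
Within each window the frame with the highest mean landmark likelihood
wins, ties going to the earliest frame so results are reproducible.

## Image enhancement

`enhance_frame()` applies a fixed chain: CLAHE (clip limit 2, 8×8 tiles)
on the CIELAB lightness channel, a saturation gain in HSV, a 5×5
Gaussian blur (σ derived from the kernel size by the usual
`0.3·((k−1)/2 − 1) + 0.8` rule), a 3×3 median filter, and unsharp
sharpening (amount 1). `boost_blue()` then amplifies pixels whose hue
lies in the dye band (default 200–260°) by a saturation **and value**
gain of 1.4. The value gain matters: dyed residue and pink mucosa have
nearly equal luminance in raw frames, and without brightening the dye
the automatic grayscale threshold clips the blur-softened blob margins
and biases fractions low by 2–3 percentage points. With it, measured
fractions track rendered ground truth to within 0.1 pp on the phantom
fixtures.

`segment_residue()` thresholds the grayscale image (Otsu by default),
then post-processes in fixed order: hole filling, removal of connected
components outside the area bounds (20 px² to 25% of the image — the
upper bound is the "large contour" filter that discards mucosa sheets),
erosion, closing, opening. The final mask is the intersection of this
threshold mask with blue-hue membership (hue in band, saturation ≥ 0.25,
value ≥ 0.15 — the saturation gate is what rejects specular glare);
either source can be used alone for ablation (`mask_combine`).

Two morphology choices are deliberate. The closing element (7 px) is
larger than the erosion element (3 px) so that a blob fragmented by a
narrow occlusion is still reconnected after erosion has widened the gap.
And because the bare erosion step otherwise shifts every mask boundary
one pixel inward — a systematic undercount of roughly one
perimeter-ring of pixels — a final dilation with the erosion element
(`compensate_erosion = TRUE`) restores that layer, making the cleanup
approximately area-preserving. Both are exposed as parameters.

## ROI geometry

All ROIs are axis-aligned, half-open integer rectangles in 0-based pixel
coordinates (x rightward, y downward), built from landmark roles
`P1..P4` that a configurable schema maps onto tracked points:

* **Glottic square** — centred on the midpoint of `P2` and `P3`; its
  diagonal is `A = V · ‖P1 − P2‖`, so the side is `A/√2`. The text this
  design follows calls `A` a diagonal; `a_is_side = TRUE` supports the
  alternative reading. A 3×3 grid is laid over the square by integer
  division, the last row/column absorbing the remainder so the nine
  cells tile the square exactly.
* **Pyriform rectangle** — width `|x_P1 − x_P4|`, height
  `V · |y_P2 − y_P3|`; one rectangle spans both sinuses.
* **Vallecular rectangle** — width `|x_P1 − x_P3|`, height
  `|y_P2 − y_P4|`.

The scale `V` defaults to 1 for both regions (no published value
exists). The rectangle formulas fix width and height but not an anchor;
the package centres each rectangle on the centroid of its four defining
points, which is symmetric and equivariant under translation and
scaling, with top-left anchoring available in the configuration.

Rounding is half-up, centre first, then side lengths. Pixel rounding
necessarily breaks exact equivariance under non-integer transforms, so
the constructors accept `round_px = FALSE` to return the continuous
rectangle; equivariance is exact there and exact under integer
translations on the rounded path. The magnified glottic view
(default ×3) is display-only: every quantitative fraction is computed at
native resolution.

## Severity grading and the invasion rule

The residue fraction of a region is the count of residue-mask pixels in
the ROI divided by the ROI area. The YPR-SRS mapping uses the published
cut points 1, 5, 25 and 50 per cent. Because the printed intervals share
endpoints ("1–5%", "5–25%"), the package closes the lower bound of each
interval — `[1,5)`, `[5,25)`, `[25,50]` — and keeps severe strictly
above 50%, which matches the printed "< 1%" and "> 50%" exactly; the
unresolvable tie at exactly 50% is configurable
(`severe_includes_50`).

For invasion, each 3×3 grid cell's fraction is computed; a cell is
*present* at ≥ 1% (mirroring the global absence cut-off — no per-cell
threshold is published). Residue in a central cell (the glottic entry;
default the single centre cell, with a centre-column option for the
slit-like entry) flags **aspiration**; residue in any other cell flags
**penetration**; both can fire, and the maximal cell is reported with a
row-major earliest tie-break. Presence-based flags are used rather than
the argmax cell alone because adding residue should never clear a flag
(the rule is monotone). Scoring uses the post-whiteout frame; the
pre-whiteout frame is retained as the baseline. Each swallow is scored
in isolation.

## What the phantom generator does and does not emulate

`make_phantom_frame()` renders: a dark pink mucosal background with
smooth illumination falloff and sensor noise, brighter pink distractor
folds, white unsaturated glare ellipses, near-uniform bright whiteout
frames, and blue residue at hue 225° placed as compact blobs with an
*exact* pixel count inside each geometry-derived ROI, so ground-truth
fractions are known to the pixel. Landmarks get isotropic Gaussian
jitter and a base-plus-noise likelihood model; whiteout frames get low
likelihoods. Everything is a pure function of spec and seed.

`make_validation_cohort()` builds labelled cases of five frames (two
clean, one whiteout, two loaded). Severity targets are drawn at least
2 pp away from the 1/5/25/50% boundaries (absence → 0%, trace → 3%,
mild U[7,23]%, moderate U[27,48]%, severe U[52,70]%), so labels are
unambiguous under small measurement error; invaded grid cells are
filled at 25%; penetration/aspiration prevalences default to 0.5,
mirroring a balanced validation set. Glare is placed outside the ROIs —
its job in the cohort is to exercise segmentation specificity, not to
occlude residue (occlusion recovery is tested separately at the
segmentation level).

The phantoms deliberately do **not** emulate photorealistic anatomy,
camera motion, compression artefacts, secretions (which can mimic
residue), or non-blue boluses. Passing the recovery tests therefore
shows that the measurement chain is correct and unbiased under
controlled optics, not that clinical performance is guaranteed.

## Validation statistics

`binary_metrics()` provides accuracy, sensitivity, specificity,
PPV (= precision; published tables sometimes print both as separate
columns, but they are the same quantity), NPV and likelihood ratios,
with divisions by zero yielding `Inf`/`NaN` markers rather than errors.
For hard label output the ROC has one operating point, so AUC is
reported as balanced accuracy, `(sens + spec)/2` — the convention under
which published AUC columns equal that mean. Cohen's kappa is
unweighted for binary outcomes and linear-weighted by default for the
ordinal scale (quadratic available); weighted kappa is implemented
directly since no installed dependency provides it, and is cross-checked
in the tests against an independent agreement-form computation and
`e1071` for the unweighted case. Fisher's exact two-sided p uses the
point-probability rule via `stats::fisher.test`, with a mid-p option
computed by direct hypergeometric enumeration. Grade-comparison rows
("mild vs. trace", "presence vs. absence of moderate", ...) restrict to
cases whose reference level is one of the two grades and dichotomize
predictions at the higher grade — an interpretation of how such table
rows are constructed, documented as such.

A small enumeration utility, `enumerate_confusions()`, searches all 2×2
tables of a given size whose rounded sensitivity/specificity/accuracy
match printed values; at n = 60 the combination 1.00/0.80/0.90 has a
unique solution, (tp, fn, fp, tn) = (30, 0, 6, 24), whose unweighted
kappa is 0.80 and PPV 0.83 — a useful internal-consistency check for
published metric rows.

## Problem sizes and numerical choices

The test suite and acceptance checks run on 256×256 phantoms
(vallecular ROI ≈ 7600 px, pyriform ≈ 7800 px, glottic square ≈ 53 px a
side), 5-frame cases and 60-case cohorts — sizes chosen so every ROI
holds comfortably more than 2000 pixels (keeping the exact-placement
error under 0.5 pp) while a full cohort analysis stays in the
minutes range on one CPU. Severity-boundary sweeps use 0.01 pp steps;
time-to-frame conversions guard against floating-point noise with a
10⁻⁹ relative epsilon; all randomness flows through explicit seeds.

## Known limitations

Single rectangles cannot separate left and right sinuses; rotated or
perspective-corrected ROIs are out of scope; secretion–residue
discrimination and subglottic residue are not attempted; kappa is
reported without confidence intervals; and the whiteout suggester is
advisory only — intervals remain a clinician input, matching the
semi-automated design the package implements.
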