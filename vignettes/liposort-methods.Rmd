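---
title: "Methods: simulating image-based liposome screening and sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating image-based liposome screening and sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(liposort)
```

`liposort` is a self-contained simulation of a microscopy-based
screening-and-sorting workflow for gene-expressing giant liposomes. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the simulation does and does
not capture about real experiments.

## Population model

A population is a mixture of clonal genotype pools combined at known volume
ratios (`population_config()`). Each liposome independently draws:

* **genotype** — multinomial with probabilities equal to the volume
  fractions. A 1:39 mix therefore contains 2.5% of the minority genotype in
  expectation, both as vesicles and as DNA template (populations are mixed
  with equal template amounts, `template_share = 1`).
* **expression** — Bernoulli with `p_expression = 0.6`. In clonal samples
  40–80% of vesicles express detectably; we use the midpoint and treat the
  flag as genotype-independent. Non-expressing liposomes still carry their
  template (they contribute DNA but no phenotype).
* **diameter** — log-normal, median 5 µm, log-sd 0.45, truncated to
  [2, 20] µm. Only the range is experimentally fixed; the log-normal shape
  and its parameters are our choice. A median of 8 µm was considered and
  rejected: with the non-overlap constraint below, 100–150 such vesicles
  exceed the random-sequential-packing limit of a 128-µm field of view, so
  the stated per-FOV densities would be unplaceable. A 5-µm median keeps
  most vesicles below 10 µm, which matches the small-vesicle regime the
  workflow targets, and packs comfortably.
* **position** — uniform in the FOV by dart throwing, with centers at least
  `r_i + r_j + min_gap_um` apart (`min_gap_um = 1`). Real liposomes can
  touch; we keep renders non-overlapping because overlap resolution is out
  of scope. Spatial clustering is not modeled.
* **dynamic mode** — determined by the genotype's phenotype: `lumen` and
  `membrane` map to the static modes; `oscillatory` draws from
  `mode_weights` (default: equal thirds pulsing / pole-to-pole / circling;
  the true mode composition of real samples is unreported, so this is a
  free parameter). Oscillatory modes get a period uniform in 15–45 s and a
  phase uniform in [0, 2π).

**Membrane fraction.** The reporter's membrane-bound fraction `m(t)`
(`membrane_fraction()`) is an artifact definition — only the mode names are
experimentally grounded: static membrane `m = 0.9`, static lumen
`m = 0.05`, pulsing a 0.9/0.1 square wave at the state's period and phase,
pole-to-pole `m = 0.9` with a Gaussian angular cap (sd 0.5 rad) whose
center flips by π each half period, circling with the cap rotating at
`2π/period`, halted with a frozen cap. These forms make pulsing change the
detector class over a 48-s time lapse while pole-to-pole and circling keep a
(partial) ring and therefore stay class 2 — reproducing the mechanism by
which class-change video selection misses some genuinely dynamic vesicles.

**Motion.** Brownian steps with per-axis scale 0.12617 µm s^-1/2, chosen so
the mean planar displacement over 10 s is 0.5 µm (Rayleigh mean
`s·sqrt(dt)·sqrt(π/2)`), matching the measured vesicle drift. Reflection at
the FOV walls keeps centers in bounds.

## Rendering model

`render_frame()` draws an ideal photon image and then applies the detector
model. Per channel:

* **membrane** — an annulus at the vesicle radius with a Gaussian radial
  profile (sigma 0.15 µm, roughly 0.3 µm wide). A hard-edged annulus mask
  was tried first and rejected: at 0.25 µm/px its rasterization leaves
  single-pixel gaps on some arcs, the ring fails to close, and hole filling
  cannot recover a disk. Per-pixel amplitude is constant, so total membrane
  signal scales with circumference.
* **protein (reporter)** — a total budget `gain × disk area` per expressing
  vesicle, split `m(t)` onto the annulus (weighted by the angular cap) and
  `1 − m(t)` uniformly over the lumen disk. The split is exactly
  conservative by construction: the weights are normalized so the budget is
  redistributed, never created, which the tests assert to 1e−6 relative.
  The per-pixel lumen brightness of a fully luminal reporter is then
  independent of vesicle size, as in a confocal section of constant
  thickness.
* **pamcherry** — lumen disks at the basal level, ×20 when photoactivated.

The ideal image is blurred with a Gaussian PSF (sigma 0.3 µm — not
experimentally reported; chosen below the smallest vesicle radius), then
Poisson shot noise, Gaussian read noise (sd 20 counts) and a constant offset
(100 counts) are applied and the result is quantized to 16 bit. Geometry:
512 × 512 px at 0.25 µm/px; pixel (row, col) is 0-based with the physical
center of a pixel at `((col + 0.5)·0.25, (row + 0.5)·0.25)` µm. Videos
render 5 frames at 0, 12, …, 48 s with Brownian updates between frames.

Not modeled: confocal axial sectioning, photobleaching, vesicle deformation,
multilamellarity, absolute intensity calibration (channel gains are free
parameters in arbitrary counts).

## Detection and localization classification

`threshold_detect()` follows the real-time analysis recipe: 3 × 3 mean
convolution, intensity threshold, connected components, hole filling, then
size (equivalent diameter 3.5–20 µm) and circularity (0.3–1) constraints;
border-touching components are dropped. The production threshold is
`median + 5·MAD` of the smoothed image (the instrument's actual threshold
value is unreported; Otsu is available as an alternative). A noise-free
image has MAD ≈ 0, where that rule degenerates to thresholding at the
background level; such images are instead cut at half their dynamic range.
Perimeter is measured on the component contour polygon; circularity
`4πA/P²` is clipped at 1 because discrete contours slightly underestimate
perimeters.

`classify_localization()` scores membrane localization with a ring score:
mean background-subtracted reporter intensity in the annulus
[0.75 r, 1.05 r] divided by the same in the disk [0, 0.6 r], background
being the image median. Class 2 is called at `R ≥ 1.5`. The radii and
threshold are artifact choices (configurable). When both signals are below
three image MADs the vesicle carries no localization information and
defaults to class 1 — without this floor, noise ratios on non-expressing
vesicles produce spurious class-2 calls. The score is invariant to affine
intensity changes up to background-estimation error.

Connected components use the labeling of the EBImage package; for
non-overlapping rendered vesicles the 4-vs-8-connectivity distinction never
changes the result.

## Tracking and dynamic-event calling

`link_tracks()` seeds tracks in frame 0 and, per later frame, assigns
candidate (track, detection) pairs within 5 µm **of the first-frame
anchor** greedily by ascending distance, one-to-one; ties under 1e−9 µm
break on the lower detection index. Unmatched detections never open new
tracks, and tracks missing a frame are dropped by default. Greedy
assignment was chosen over optimal bipartite matching for speed; on sparse
instances (spacing ≥ 12 µm, drift ≤ 1 µm/frame) it is asserted equal to
exhaustive minimum-total-distance matching. Matching to the previous frame
instead of the anchor is available as a config switch for comparison. A
track is **dynamic** iff its class sequence contains both classes; for
full-length 5-frame tracks this coincides with adjacent-pair comparison.

`select_targets()` implements the two stimulation policies: `center_only`
(at most one target per FOV — the qualifying object nearest the FOV center
within 20 µm, matching point stimulation at the center coordinate) and
`anywhere` (all qualifying objects).

## Photoactivation and FACS

`photoactivate()` activates every target with probability 1 (all target
vesicles are successfully tagged in practice) and every non-target within
15 µm independently with `p_off`. Expected spatial precision over many
stimulations is `1/(1 + n̄·p_off)` with `n̄` the mean neighbor count inside
the radius; `calibrate_p_off()` estimates `n̄` by Monte Carlo at 100
vesicles/FOV and inverts this for the measured precisions (96/89/86% at
34/84/167 µW). Axial off-target activation is folded into the planar
probability, since most vesicles sit in one z-plane.

`facs_measure()` recovers each vesicle as an event with probability 0.15
(the 10–20% recovery band, modeled size-independent), with intensities
proportional to vesicle volume times multiplicative lognormal noise
(CV 0.3): reporter ∝ expression (non-expressing events sit at a 2%
autofluorescence floor), pamcherry ∝ ×20 when activated.

**Gate design.** The natural idea of placing the sort gate in the valley
between the basal and activated intensity modes fails under this intensity
model: volume spans three decades (log-sd ≈ 3 × 0.45 = 1.35), larger than
the ln 20 ≈ 3.0 activation gap relative to the combined spread, so the two
modes overlap and no valley exists. `derive_gates()` instead does what a
flow operator does: it places the pamcherry gate just above the brightest
event of a non-stimulated control sample (default margin ×1.1). The price
is sensitivity — only activated vesicles large enough to clear the largest
basal vesicles pass — which the simulation accepts as the analogue of the
low FACS recovery of photoactivated vesicles. The reporter gate (used only
for quadrant reporting) is a 2-means split on the log scale. Quadrants are
Q1 (reporter-high / pamcherry-high) through Q4; sorted events are the
pamcherry-high ones, and FACS precision is Q1/(Q1+Q2).

## Quantification

`fractions_and_fold()` computes per-genotype fractions pre/post sort and
fold enrichment `frac_post/frac_pre`; a zero presort fraction is flagged
rather than reported as infinite, and per-replicate folds are computed
before averaging. `fit_standard_curve()` regresses Cq on log10
concentration over the 1e−5–100 pM calibration range; a perfect-doubling
assay gives slope −1/log10 2 ≈ −3.3219, and efficiency is reported but not
used to correct concentrations. `filter_reads()` keeps 1100–1400 bp.

`count_variants()` replaces read mapping with exact 12-nt flank anchoring
around the 6-nt MTS window, searched in both orientations via reverse
complement. Reads with missing, ambiguous, or mis-spaced anchors, or an N in
the window, are discarded into QC counts; substitution errors inside a
flank therefore discard the read, a deliberate trade of yield for
desk-scale determinism with no external index. The shipped 1398-bp
reference amplicon is synthetic (only its length, window position and flank
uniqueness matter); the 9-variant library marks Var1 (wild type, FL) and
Var7 (LH) as functional membrane binders. Beyond the N/ambiguity filter, no
further quality control is applied to extracted windows.

## Orchestration, determinism and problem sizes

`run_experiment()` runs simulate → render → detect (→ track) → select →
photoactivate → FACS → gate/sort → quantify per replicate, writing a run
directory (config, per-stage CSVs, JSON report, log). Every stage seed
derives from the experiment seed, so identical seeds give byte-identical
reports; a failing replicate is logged and skipped.

The presets run tens of fields of view per replicate (150 for the
mock-library sort, fewer for the others) rather than the thousands of a
real session. These sizes are chosen so that a full three-replicate
mock-library experiment sorts a few dozen vesicles — enough for stable
post-sort fractions — while a complete run finishes in minutes on one core.

## What passing tests do and do not show

The synthetic data are cleaner than real images: no multilamellar or
deformed vesicles, no focus drift, no debris, uniform background, perfectly
circular vesicles, and a detector whose noise model is known. Detection
precision/recall ≥ 0.95 on sparse synthetic FOVs therefore says the
geometry pipeline is correct, not that real-data performance would match a
trained detector (which reaches ~80% on real images). Likewise the
enrichment figures produced by the simulated pipeline test the *logic* of
selection, tagging, gating and counting under the stated noise models — not
the biology of encapsulation or expression, which enter only through the
fixed probabilities documented above.
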