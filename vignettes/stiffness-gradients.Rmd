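---
title: "Closed-loop stiffness gradients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop stiffness gradients: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffgrad)
```

## The problem

Dose–response studies of 3D cell cultures need many microenvironments of
graded mechanical stiffness. One way to produce them is a droplet
microfluidic device in which two alginate solutions — a soft stock
(0.75% w/v, carrying Ca-EDTA and 125 nM FITC-dextran) and a stiff stock
(3% w/v, carrying Zn-EDDA and 625 nM FITC-dextran) — co-flow into a
flow-focusing junction where a continuous oil phase pinches them into
monodisperse droplets. The fraction of the channel width occupied by the
stiff stream, written $f_{high}$, sets each droplet's composition by
linear volumetric mixing. Competitive ligand exchange between the two
chelator systems releases Ca²⁺ and gels the alginate, but only droplets
carrying at least 20 mM of *each* divalent ion (at the default 200 mM
stocks, $0.1 \le f_{high} \le 0.9$) crosslink into stable beads. The
trapped FITC-dextran (2 MDa, too large to escape the gel) encodes the
alginate concentration — and therefore the stiffness — of every bead.

Because alginate is hundreds of times more viscous than water, the
delivered flows respond sluggishly and unpredictably to pump commands, so
open-loop scheduling of flow rates fails. The toolkit reproduces, at desk
scale and fully in simulation, the closed-loop alternative: a shallow CNN
watches the laminar interface at the junction and a state machine nudges
the two aqueous pumps until the interface sweeps back and forth, producing
repeated concentration gradients. Downstream, a high-content-style assay
detects the fluorescent beads and bright-field spheroids, converts bead
fluorescence to alginate concentration and stiffness, and compares
spheroid growth across stiffness bins.

Everything here runs against synthetic data produced by the package's own
seeded generators; no external data are used.

## The control loop

**Sensing.** Frames of 120×120 px are acquired at 50 Hz at the junction.
The laminar boundary is visible as a refractive-index edge; the generator
renders it as a sigmoidal step (≈1 px wide) topped by a narrow bright
refraction line, with dark elliptical cells (8–15 px) that may sit on the
interface, illumination tilt, and Gaussian noise. A shallow CNN — three
3×3 convolution + 2×2 max-pool stages (8/16/32 filters), a 64-unit dense
stage and a two-way softmax — classifies each frame as LOW_VF
($f_{high} < 0.2$) or HIGH_VF ($f_{high} \ge 0.8$). Fewer than three
convolution stages do not yield reliable models, so the stage count is
fixed; the widths are configurable and were chosen for sub-minute CPU
training. Each image is standardised to zero mean and unit variance
before the forward pass, which makes predictions exactly invariant to
affine illumination rescaling. Training uses mini-batch Adam
(lr $10^{-3}$, batch 32) on ~600 frames (300 per class, stratified 70/30);
on one CPU this takes well under a minute and a forward pass takes a few
milliseconds, inside the 20 ms frame budget.

**Windowing.** Binary predictions are averaged over disjoint 50-frame
windows, so flow rates update once per second. The window's population
standard deviation (bounded by 0.5 for a fixed-length 0/1 window — the
reason the population rather than sample estimator is used) doubles as an
"appearance is unlike either trained class" signal: it exceeds 0.4 exactly
when the window mean lies strictly between 0.2 and 0.8.

**Decision rules.** While SEEKING a target class, the pump driving toward
the target steps up 1 µL/min per second and the opposing pump steps down
(3 µL/min when reducing the viscous high-concentration line, else
1 µL/min). When the window mean toward the target reaches 0.95, the
controller OVERSHOOTs: same-direction stepping continues for at most 10 s,
ending early if the window standard deviation exceeds 0.4. The target
then flips and SEEKING resumes; every LOW↔HIGH alternation pair counts as
one completed gradient. Commands are clipped to 6 µL/min (high pump) and
13 µL/min (low pump) with a 0.5 µL/min floor (pumps cannot run backward
and a dead stream would collapse the interface), and the dispersed-phase
sum is kept below half the 30 µL/min oil flow to preserve monodispersity;
when the sum bound binds, the pump stepped up most recently is reduced.
The "95% confidence" criterion is interpreted as the *window mean*, not
per-frame softmax confidence, because the averaging step immediately
precedes the criterion in the protocol; this choice is fixed and
documented rather than configurable. If a pump saturates before the
target is reached, it holds at its limit while the other pump keeps
stepping.

**Plant.** The simulated plant gives each pump a first-order lag
($\tau_{low} = 1$ s, $\tau_{high} = 4$ s — the viscous line is slower;
both config-exposed), integrated exactly per step, plus optional
zero-mean jitter (2% of command) on the delivered flows. The realised
interface fraction defaults to the equal-mobility model
$f_{high} = Q_{high}/(Q_{low}+Q_{high})$, with an optional
viscosity-weighted variant. Droplets are emitted at a constant 200 Hz
(a `rate(Q)` hook exists but is not the default — the study regime holds
the oil flow constant), with volume from a 106 µm diameter, Poisson cell
loading $\lambda = \rho V \approx 3.7$ cells/droplet at
$6\times10^6$ cells/mL (bench experience usually rounds this to "about
3"), and composition from the linear mixing rule at the instantaneous
realised $f_{high}$.

With the trained CNN in the loop the realised fraction sweeps from below
0.1 to above 0.9 every cycle (~30 s per gradient), comfortably covering
the $[0.15, 0.85]$ span asserted in the tests.

## The assay

**Detection.** Instead of a full YOLO-class network, detection uses a
deliberately compact single-stage grid detector with the same analytical
role and interfaces: candidate centres on a 16 px grid; per-cell features
are 8×8 block means of a 96 px patch plus signed horizontal/vertical
extent profiles (band means right/left/below/above the centre), extracted
in C++; a ridge-regularised logistic regression scores objectness and
ridge regressions decode the centre offset and box size, with one
refinement pass at the predicted centre and greedy IoU NMS plus a
concentric-duplicate sweep. One class per model (beads; spheroids).
Training on ≥40–50 annotated synthetic fields reaches held-out AP(0.5)
above 0.9 for beads; the ridge penalty defaults to 1 because the
objectness problem is near-separable at these sizes and unregularised
IRLS diverges. Cells inside an object but more than one grid cell from
its centre are kept as negatives — the signed profiles make off-centre
patches linearly distinguishable — while the centre cell's immediate
neighbours are ambiguous and excluded from the objectness loss.

**Bead fluorescence.** Per-bead intensity is the mean over a disc eroded
to 0.8 of the radius inscribed in the detection box, minus the image
background (median outside all boxes), clamped at zero. Erosion is
unbiased here because the dye distribution inside a bead is uniform,
and it makes the estimate robust to small box-regression errors that
would otherwise mix background into the mean.

**Calibration.** A Gaussian is fitted by least squares to the intensity
histogram; its 5th/95th percentiles ($\mu \mp 1.6449\sigma$) are anchored
at 0.7 and 2.8 % w/v, and a line through the anchors converts intensity to
concentration. Fitted (not empirical) percentiles keep the anchors stable
across days with different focus and background. The fit is bounded:
$\mu$ within the data range and $\sigma$ at most 1.5 times the sample
standard deviation; genuinely Gaussian data are unaffected, while flat or
bimodal histograms (which gradient runs produce, since the controller
dwells at the sweep extremes) would otherwise admit degenerate very wide
solutions. Note the
anchors deliberately sit *outside* the crosslinkable composition range
(linear mixing bounds true concentrations to [0.975, 2.775]% inside the
ion window): the convention attributes the extreme fluorescence tails to
the softest and stiffest gels. Stiffness comes from a quadratic
$G'(c) = a c^2 + b c$ through (0.7%, 50 Pa) and (2.8%, 1000 Pa) — solved
exactly in the two-point case (no intercept is imposed, and none is
identifiable from two points), least-squares with intercept when a fuller
rheology table is supplied — and must be strictly increasing over the
anchored range.

```{r stiffness}
m <- fitStiffnessModel()
stiffnessFromConcentration(m, c(0.7, 1.75, 2.8))
```

**Spheroid measurement and statistics.** Spheroid diameter is the mean of
box width and height over the pixel size; detections with aspect ratio
(height/width) outside the inclusive band [0.7, 1.3] are discarded as
irregular or fused. Each spheroid is assigned to the nearest bead centre,
and must lie inside that bead's box (the association rule is a package
choice; nothing in the protocol prescribes one). Measurements are binned
into 8 equal-width stiffness bins (equal-count available), bins with
fewer than 65 spheroids are flagged out of the test, and a Kruskal–Wallis
omnibus test compares diameters across qualifying bins at α = 0.05 — the
protocol reports median comparisons without naming a test, and
Kruskal–Wallis is the standard omnibus choice for that readout. A
degenerate input with identical diameters returns H = 0, p = 1 rather
than an undefined statistic.

## What the generators emulate — and what they do not

The synthetic junction frames reproduce the geometry (120×120 px, 50 Hz),
a localisable but soft interface, occluding cells and illumination drift;
they do not model diffraction, defocus stacks or droplet-in-oil optics.
Interface localisability is tested by brute force: for clean frames the
maximum column-gradient position equals $f_{high} \times 120$ within 1 px
across the whole fraction grid. Bead fields are hard-edged discs with
intensity proportional to FITC content over a configurable
signal-to-noise range, plus two bead-level brightness effects observed in
real bead populations: a log-normal per-bead factor (sd 0.10) for
ordinary variation in dye retention, and a small fraction (8%) of
strongly dimmed beads representing incomplete crosslinking and dye
leakage — the low signal-to-background cases that defeat classical
segmentation and motivate a learned detector. Spheroid fields are
textured dark ellipses with contrast jitter. Because the low calibration
anchor lies below the narrowest crosslinkable composition (linear mixing
bounds true stiffness to ~[106, 982] Pa inside the ion window), the
assigned stiffness range extends below ~100 Pa only through this
bead-level variability — with it, an end-to-end run spans from below
60 Pa to above 900 Pa, the soft-gel breadth the assay is meant to
resolve. The calibration round-trip test runs with both brightness
effects disabled, as a controlled condition isolating the detection +
calibration chain; with them enabled the brightness variability itself
becomes the dominant, irreducible part of the per-bead concentration
error. Passing tests therefore demonstrate
the correctness of the control loop, detector and calibration machinery
on data with these statistics — not performance on real micrographs,
where appearance variation is far richer.

Cell-count statistics of the frames (density, contrast) are not reported
for the real system; defaults (Poisson mean 1.5 cells/frame, noise sd 4)
were chosen so that the classification task is learnable yet the Canny
baseline degrades visibly under occlusion, and they are exposed in the
generator config.

## Numerical choices and degenerate inputs

* RNG: every generator seeds a Mersenne–Twister stream locally and
  restores the caller's state; identical arguments give bit-identical
  output. Pipeline stages fan seeds out deterministically from one master
  seed (all below $2^{31}$).
* Class ties (softmax 0.5/0.5) break toward LOW_VF.
* The normal 95% quantile is `qnorm(0.95)` = 1.644854.
* `windowEstimate` rejects windows that are not exactly 50 binary values.
* The Canny baseline (σ = 1.5, hysteresis at 0.1/0.3 of the gradient
  dynamic range, column-histogram voting with a 5-column pool) returns an
  explicit failure state on uniform images, vote-starved columns, or two
  well-separated peaks of comparable weight; failures count against it in
  the benchmark.
* Truncated-normal draws (bead diameters) resample until positive.
* A non-monotone stiffness fit, a degenerate (σ = 0) intensity sample,
  fewer than 50 calibration intensities, fewer than two qualifying bins,
  and AP without ground truth all raise errors rather than returning
  quietly wrong numbers.
* The closed loop aborts with a stage diagnostic if the configured
  simulated-time cap (600 s) passes without completing the requested
  gradients.

## Problem sizes

Defaults throughout are desk-scale choices that keep any single check in
the seconds-to-a-couple-of-minutes range on one CPU while preserving the
study's protocol constants: ~600-frame classifier datasets, two- to
three-gradient loop runs, 50-field detector fixtures of 20 beads each,
1,000–2,000-bead populations for recovery checks, and 200-repeat
simulations for test-level calibration. The full-throughput bookkeeping
check (200 Hz × 5 min = 60,000 droplets) runs vectorised in one call.

## Known limitations

* The detector is linear on pooled features: adequate for discs and
  ellipses on clean backgrounds, far below a convolutional detector on
  textured real images; its role is analytic parity (same interfaces,
  same evaluation), not feature parity.
* The plant is a first-order lag with a constant droplet rate — no
  capillary physics, surfactant dynamics or gelation kinetics.
* Spheroid growth is not modelled over time; day-series attrition
  (bead loss per resuspension) is exposed only as an optional parameter.
* The hybrid two-hydrogel (agarose/alginate) mode and confocal
  volumetry are out of scope.
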