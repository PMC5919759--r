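---
title: "Methods: quantifying capillary obstruction, fate, and rarefaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying capillary obstruction, fate, and rarefaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capfate)
```

# The scientific problem

Cortical capillaries — the ~3–5 µm lumen vessels that do the brain's
gas and nutrient exchange — occasionally clog: a red blood cell,
leukocyte, or embolus stalls in a segment and flow stops. Most
obstructions clear within a day, either by washout of the embolus back
into circulation or, rarely, by angiophagy (extrusion through the
endothelial wall). A substantial minority of obstructed segments are
instead pruned: the endothelium retracts stepwise and the segment is
eliminated, with no compensatory sprouting. Because obstruction is an
ongoing stochastic process, the slow accumulation of pruning events is
a candidate mechanism for the microvascular rarefaction that
accompanies brain aging.

`capfate` implements the complete quantitative chain behind that
argument: measuring flow in single capillaries, counting capillaries
in imaging volumes, accounting for the fates of tracked obstructions,
estimating obstruction incidence, simulating the long-run consequence,
and scoring the endothelial shear-stress signal (phosphorylated
VEGF-R2) around obstruction sites. Raw imaging data are replaced by a
synthetic-data module with exact ground truth, so every stage is
testable offline.

# Line-scan velocimetry

A line scan repeatedly samples a 1D line along a capillary axis.
Moving RBCs exclude the plasma dye and trace dark diagonal streaks in
the (time × space) image; a streak's slope in (time, distance)
coordinates is Δt/Δx, and velocity is its reciprocal. We read the
protocol's "inverse slope (Δtime/Δdistance)" as: the measured slope is
Δt/Δx (ms/µm) and the reported velocity is its reciprocal — the only
reading consistent with velocities in µm/s.

`estimate_rbc_velocity()` supports two routes with the same estimand:

* **Manual streaks** (parity with human raters): traced points per
  streak, a straight-line fit per streak, velocities averaged.
* **Automatic detection**: the contrast-inverted image is sheared by a
  candidate per-line displacement and averaged over lines; the
  displacement maximizing the variance of the aligned profile is the
  dominant streak orientation. Individual streak trajectories are then
  extracted around the aligned peaks and re-fit; by default three
  equally spaced streaks are measured, mirroring the manual protocol.

Numerical choices:

* **Curvilinear exclusion**: a streak with linear-fit R² < 0.9 is
  excluded (the operationalization of the qualitative "curvilinear
  slopes were excluded" rule). A zero-variance trajectory (vertical
  streak, stalled cell) is treated as perfectly straight, since R² is
  undefined there.
* **No-flow flag**: a scan with no detectable dark structure (no
  streaks) is an obstructed capillary and is flagged `no_flow` rather
  than reported as v = 0. v = 0 with visible vertical streaks is a
  distinct, valid measurement.
* **Averaging contract**: the estimate over several scans is the mean
  of per-streak velocities, so 3 scans × 3 streaks equals the mean of
  the 9 single-streak estimates exactly.

Lumen diameter is the full width at half maximum of a Gaussian + constant
baseline fitted to a perpendicular intensity profile
(FWHM = 2√(2 ln 2)·σ ≈ 2.3548 σ), fitted by direct least squares
(`optim`; `nls` fails on zero-residual noiseless profiles). Flux assumes
laminar flow: F = (π/8)·v·d².

# Capillary census

The census re-implements the original ImageJ macro: stacks are split
into substacks of 10 slices (20 µm at the 2-µm z-step; a trailing
partial substack is kept and weighted by its true depth), each substack
is maximum-projected, auto-thresholded with the Triangle method on a
256-bin histogram over the projection's range, despeckled with a
radius-1 median filter (the macro's order — threshold first — is the
default; the reverse order is available), and skeletonized by 2D
topological thinning (Zhang–Suen). Per substack: vascular volume =
projected area fraction × physical substack volume; length = skeleton
pixel count × pixel pitch; width = area / length (aggregated as a
length-weighted mean). The capillary count is total vascular volume
divided by the canonical single-capillary volume π·2²·75 = 942.48 µm³.

The Triangle, Yen and Moments thresholds are hand implementations of
the published algorithms in their ImageJ-compatible formulations
(cross-checked against scikit-image during development). Two artifacts
of those formulations are worth knowing: on an exact two-delta
histogram Yen's criterion ties identically across the valley (argmax
falls at bin 0) and the Moments p0-tile lands on the upper delta; with
modes of any finite width both behave as expected.

**Known bias, by design.** Projecting a substack and multiplying by its
depth treats vessels as square prisms: volume is overestimated and
z-direction length is lost. For a vessel lying in the imaging plane the
inflation is roughly substack depth / vessel diameter (~5× at 20 µm /
4 µm); for a vessel crossing the plane the conversion is nearly
unbiased. The package reports the bias direction and does not correct
it. Consequently the validation phantoms used for count-accuracy tests
are built from near-axial cylinders (tilt ≤ 3° from the z-axis), where
the automated count lands within ±1–2 of truth; an in-plane cylinder
phantom is used separately to demonstrate the documented bias
directions (volume over-, length under-estimated). A green census test
therefore establishes correctness of the pipeline's arithmetic and its
behavior on favorable geometry — not unbiasedness on arbitrary
orientations, which the method does not claim.

# Obstruction fates

Tracks are longitudinal records of single obstructed capillaries.
Eligibility mirrors the imaging protocol: at most one lodged
microsphere, and at least two branching points from the nearest other
obstruction. The fate summary at a horizon (default day 21) classifies
each track by terminal status — pruned, or intact via washout or
angiophagy; a track pruned after transiently regaining flow counts as
pruned. Recanalization curves are computed per animal (percent of that
animal's time-0 obstructions still obstructed) and then averaged across
animals, matching the stated per-animal normalization; fate summaries
are over pooled tracks, also as stated.

Obstruction incidence has two estimators: the survey form
(`n_obstructed / n_sampled` scaled from the observation window to 24 h,
e.g. 2/20,334 in 2 h → 0.118%/day) and the density form
(obstructions/mm³ against ~20,000 capillaries/mm³; 3.69/mm³ over 3 h
gives 0.1476%/day unrounded — the function deliberately returns the
unrounded value).

Per-branch-order risks follow from the identity r_o = R·g_o/f_o, where
f_o is the fraction of capillaries at order o, g_o the fraction of
obstructions there, and R the overall daily rate; Σ f_o·r_o = R is
enforced to numerical precision. Branch orders count branching points
from the penetrating arteriole (order 0), stated once and used
everywhere.

# The rarefaction model

A theoretical population (default 100,000 capillaries, each with a
fixed branch order, no structural relationships) evolves in 2-hour
cycles. Per cycle and order, the expected loss is
N_o · r_o,cycle · p, with r_o,cycle = r_o · cycle/24 (linear small-rate
scaling) and p = 0.30 the pruning probability. Obstructions that are
not pruned revert to flowing within the cycle — that is the literal
arithmetic of the published update rule, so there is no obstructed
carry-over state. The Monte-Carlo mode replaces the expectation with
Binomial draws (obstructed ~ Bin(N_o, r_o,cycle), pruned ~
Bin(obstructed, p)) and is unbiased for the expected-value trajectory.
In the homogeneous case the trajectory has the closed form
(1 − R·(cycle/24)·p)^cycles, used as an oracle in the tests.

Two structural facts shape the predictions. First, with R = 0.118%/day
and p = 0.30, one year gives 1 − (1 − R/12·0.3)^4380 ≈ 12% density
loss. Second, by Jensen's inequality any mean-preserving spread of risk
across orders weakly *increases* overall survival, because the
per-order survival curve is convex in the rate: the homogeneous 405-day
value (86.64% remaining) is a floor, and concentrating risk at low
orders pushes the prediction toward ~87–89%.

**The packaged branch-order table is an estimate.** The measured
distribution behind the original 405-day prediction of 88% remaining is
not reproduced in text (it lives in the study's supplementary
database), so `default_branch_order_table()` encodes a figure-level
reconstruction chosen once: a broad all-capillary distribution over
orders 1–8 (mean near order 4–5) and an obstruction distribution
concentrated at low orders with a peak at order 3. With it the model
leaves ~87.3% after 405 days — inside the Jensen bracket [86.6%, ~89%]
and within a point of the published prediction. Headline analyses
accept a user-supplied table for exact replication.

# Coverage scoring

Around each obstruction site a square ROI spanning 15 µm on either side
is placed (the protocol does not state the ROI shape; a box is chosen
for determinism). Channels are median-filtered (radius 2) and
auto-thresholded (Triangle for the endothelial channel, Yen by default
for the signal channel; Moments available, since the protocol names
both without a rule). Coverage is signal-AND-vessel pixels over vessel
pixels × 100; restricting signal to the vessel mask is algebraically
the stated "invert the vascular mask and subtract" operation. A
coverage at or above the 20% cutoff classifies a recanalized capillary
as high-signal (boundary to "high", the conventional reading of a
cutoff separating an upper population). Endothelial nuclei are counted
within 100 µm of a site when their footprint lies entirely on the
vessel mask.

One exactness caveat, made deliberately: a radius-2 median filter
necessarily erodes interior corners of any finite signal region, so no
intensity-pipeline can return a scattered pixel quota *exactly*.
`vascular_coverage()` therefore accepts pre-binarized logical channels
and uses them as-is; quota fixtures are exact along that path, while
the full intensity pipeline is validated with tolerance on contiguous
("block") fixtures.

# The synthetic-data generators

The generators state a world and keep it fixed:

* **Vessel phantoms**: cylinders rasterized by the voxel-center rule (a
  voxel belongs to a vessel iff its center is inside the cylinder),
  optional Gaussian blur, and a Poisson–Gaussian noise model
  (shot noise scaled by a photons-per-unit gain plus Gaussian read
  noise) — standard for photon-limited two-photon imaging, without
  claiming the original protocol specified it. Ground truth is always
  the analytic geometry (Σ πr²L), never the rasterization, so noise
  settings cannot move it.
* **Line scans**: dark streaks on bright plasma (RBCs exclude the
  dextran dye), displacement per line = v · line period / pixel pitch;
  v = 0 gives vertical streaks; displacement beyond the scan width is
  rejected as aliasing. The original protocol does not state lines per
  scan or pixels per line; defaults (256 × 64 at 1 ms and 2 µm) are
  free parameters chosen for realistic streak counts.
* **Fate tables**: terminal fates drawn with p(prune) = 0.30 and
  p(angiophagy) = 3/162; 162 tracks over 14 animals at imaging days
  0, 0.25, 0.5, 1, 2, 4, 10, 15, 21. Clearing hazards are front-loaded
  so ~75–80% of obstructions clear within 24 h (the stated band);
  pruning is restricted to day ≥ 2; 25% of pruned tracks transiently
  regain flow first (the phenomenon is documented, its frequency is
  not — the value is a one-time choice). A deterministic quota mode
  instantiates the exact published composition 49/110/3 for worked
  examples. The last hazard interval is forced to 1 so every track has
  a terminal fate at the horizon.
* **Coverage fixtures**: the signal quota is an exact pixel count on
  the vessel mask.

What a green test does *not* establish: the generators produce
disconnected ideal cylinders, straight streaks, and binary-quota
masks — no network topology, no pulsatility, no staining variability.
They validate the estimators' arithmetic and contracts, not robustness
to every property of real imaging data.

# Reproducibility and limitations

All stochastic functions take explicit seeds and restore the caller's
RNG state; fixed seeds give bit-identical outputs. Known limitations:
the census is not a general vessel segmenter and does not correct its
projection bias; the rarefaction model has no flow rerouting or
inter-capillary dependence and constant risks over time; the coverage
module models no antibody biology. Group statistics (t-tests, ANOVAs)
of the original study are out of scope throughout.
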