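---
title: "Signal drift in brain dMRI and its effect on IVIM estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal drift in brain dMRI and its effect on IVIM estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimdrift)
```

## The phenomenon and the modeling choices

Magnitude dMRI of the brain shows a slow, multiplicative intensity drift
over the course of a scan: on the order of 1–2 % per 5 minutes brain-wide,
rising above 5 %/5 min frontally, with a spatial gradient that typically
runs from negative drift in frontal regions to positive drift around the
cerebellum. Its physical origin is not settled (B0 drift, flip-angle drift,
off-resonance changes have all been implicated), which is why this package
implements *retrospective* corrections driven by b = 0 volumes interspersed
through the acquisition, rather than any physics-based prospective model.

Three corrections are implemented, all second-order polynomials in the
acquisition index $n$ fitted to the b = 0 subset by least squares:

* **global**: one polynomial $k_0 + k_1 n + k_2 n^2$ for the masked median
  signal;
* **voxelwise**: the same polynomial independently per voxel;
* **spatiotemporal**: $p_0(x,y,z) + p_1(x,y,z)\,n + p_2(x,y,z)\,n^2$ with
  each $p_i$ a complete second-order spatial polynomial, i.e. all products
  $n^i x^a y^b z^g$ with $i,a,b,g \in \{0,1,2\}$ — exactly 81
  coefficients — estimated by iteratively reweighted least squares with the
  Tukey biweight after voxelwise division by the first b = 0 volume (which
  removes the anatomical signal distribution from the regression target).

The correction divides *all* volumes, at every b-value, by the fitted
field. The working assumption — supported by the slope analysis
`drift_slope()` makes possible on protocols that re-acquire the same
direction at b > 0 — is that drift measured at b = 0 applies
multiplicatively at all b-values.

A global correction is structurally unable to fix a spatially antisymmetric
drift: if one pole of the brain drifts at +5 %/5 min and the other at
−5 %/5 min, the whole-mask median barely moves and the fitted global
polynomial is flat. The package's acceptance suite demonstrates exactly
this contrast (global reduction of pole drift < 10 %, voxelwise and
spatiotemporal ≥ 90 %).

### Numerical choices in the spatiotemporal fit

The bisquare details are not uniquely fixed by the robust-regression
literature, so the package pins them explicitly: tuning constant 4.685,
robust scale 1.4826 × MAD of the residuals re-estimated each iteration,
at most 50 iterations, convergence when the maximum coefficient change is
below 1e−8 relative to the largest coefficient. A zero robust scale
(exactly self-consistent data) terminates immediately. Spatial coordinates
are voxel centers affinely mapped to $[-1, 1]$ over the mask bounding box —
raw voxel indices raised to fourth-order products would make the design
badly conditioned. The temporal variable is the acquisition index, not wall
time; for the constant-interval schemes here the two are proportional. The
fit refuses masks providing fewer than 5 × 81 b = 0 samples. Voxels where
any fitted polynomial turns nonpositive are dropped from the model mask
with a warning.

Equation-wise the correction divides by an *un-normalized* polynomial with
signal units; `ivimdrift` instead normalizes every evaluated field to 1 at
the first b = 0 acquisition, so corrected data keep the physical scale of
that acquisition. IVIM estimates are invariant to this choice (the fitted
$S_0$ absorbs any global scale), but downstream steps that compare absolute
signal levels (the FC/NC median normalization) are cleaner for it.

## The synthetic phantom

`make_phantom()` builds an ellipsoidal "brain" with piecewise-smooth
parameter maps in brain-like ranges — D 0.6–1.0 µm²/ms, f 1–6 %,
D* 5–30 µm²/ms, v_d 0.5–3 mm/s, S0 500–1500 — and three cubic ROIs at the
anterior, superior-central, and posterior-inferior poles, standing in for
prefrontal white matter (PFWM), centrum semiovale (CS), and cerebellum
(CB). `make_drift_model()` constructs a multiplicative drift field *inside
the 81-coefficient family*:

$$\mathrm{field}(n;x,y,z) = 1 + \frac{R(x,y,z)}{100}\,
\frac{t_\mathrm{last}}{300\,\mathrm{s}}\left[(1-\kappa)\tau +
\kappa\tau^2\right],\qquad \tau = t_n / t_\mathrm{last},$$

with $R$ (in %/5 min over the full scan) affine in space, interpolating the
requested pole targets at the ROI centroids, and $\kappa$ a temporal
curvature fraction (default 0.3; 0 gives purely linear drift). The field is
exactly 1 at $n = 0$ and meets the pole targets exactly at end of scan. An
optional seeded second-order spatial "wobble", projected to vanish at both
poles, makes the field less idealized without moving the ROI targets.
Default targets are −5 %/5 min frontal and +5 %/5 min
posterior-inferior, matching the magnitude and sign pattern reported for
the human brain. Noise is Rician (`sqrt((S+e1)^2 + e2^2)`), the natural
model for magnitude MRI; the acquisitions' true SNR is not known, so SNR
is a free simulation parameter (100 at b = 0 in the standard conditions
used by the tests and the acceptance script).

What the phantom does *not* emulate: anatomy (no tissue classes, no CSF),
motion, eddy currents, susceptibility distortion, partial volume, or any
drift outside the second-order family. Consequently, passing tests show
that the algorithms are implemented correctly and behave as designed under
in-family drift and Rician noise — not that a second-order polynomial
suffices for any particular scanner's drift.

## Acquisition schemes

Two looping structures matter:

* **mixed** (drift-robust): loop through b-values and the six encoding
  directions $x, y, z, -x, -y, -z$ with simultaneous increments, advancing
  an extra direction offset each time a full lcm cycle completes so every
  (b, direction) pair is covered. b = 0 entries carry a null direction but
  consume a direction slot. The printed protocols follow: sIVIM uses the
  within-cycle sequence 0, 200, 800, 200, 0, 200 s/mm² (repetitions 2, 3, 1,
  from a Cramer–Rao-bound optimization taken here as a preset), the
  diffusive and ballistic protocols interleave their sorted b-values in
  "low–high" order (0, 800, 5, 500, … and 0, 200, 5, 100, …).
* **ordered** (drift-sensitive): ascending b, directions in canonical
  succession — the order that converts drift into parameter bias.

The exact scanner interleaving when the sequence length shares factors with
6 is not recoverable from protocol descriptions; the lcm-offset rule is one
consistent reading that achieves the stated goal (all combinations,
distributed over the scan). Volume interval is 7.5 s for all three presets
(each preset's scan time divided by its volume count: 270 s/36, 450 s/60,
630 s/84); per-volume timing beyond that is not modeled.

The ballistic non-flow-compensated scheme needs flow-encoding factors $c$;
gradient-waveform timings are out of scope, so the preset uses a *synthetic*
table $c = 0.35\sqrt{b/200}$ s/mm — the $\sqrt{b}$ shape follows from
scaling gradient amplitude at fixed timing, and the 0.35 s/mm ceiling makes
$c\,v_d$ order-one over the phantom's velocity range, i.e. the attenuation
$e^{-c^2 v_d^2}$ is informative. Real analyses should supply measured
c-values via the cval sidecar.

## The acquisition-order simulation

`simulate_ordered()` reproduces the logic used to study order effects on
real data: take data corrected with the spatiotemporal model, permute the
volumes into ascending-b order, then *re-impose* the drift by multiplying
with the same model evaluated at the new indices. The result is an
uncorrected series "acquired" in ordered fashion under the identical drift
field, directly comparable to the uncorrected mixed series.

With negative frontal drift, ascending-b ordering attenuates the late
high-b volumes extra, which steepens the apparent decay: frontal D and f
from the ordered series systematically exceed their mixed-series
counterparts (the acceptance suite shows 10/10 seeds concordant for both).
For the corrected comparison the ordered series is corrected with the same
spatiotemporal model that generated it — the b = 0 volumes of an ordered
protocol all cluster at the start of the scan, so *refitting* a quadratic
there and extrapolating to the end of the scan would be ill-posed; this is
precisely the argument for interspersing b = 0 volumes. Corrected mixed and
corrected ordered data are then the same volumes in different order, and
the ordering effect vanishes identically.

## IVIM estimation details

All estimators run on geometrically direction-averaged data (the geometric
mean keeps log-linearity and mitigates background-gradient cross terms);
b = 0 repetitions are averaged the same way. For the ballistic protocol the
FC and NC scans are each divided by their own masked median b = 0 signal
before being combined, removing scaling differences between scans.

* `fit_sivim()` is closed-form. The segmented estimate is *biased* on
  biexponential data: residual pseudo-diffusion signal at b = 200 s/mm²
  steepens the apparent (200, 800) slope, inflating D and deflating f, with
  both approaching truth as D* grows. The test suite asserts this computed
  direction.
* `fit_diffusive()` and `fit_ballistic()` use bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`, numeric Jacobian, ftol/ptol 1e−10, ≤ 200
  iterations) per voxel. Bounds: D ∈ [0.1, 3.5] µm²/ms, D* ∈ [5, 100]
  µm²/ms, f ∈ [0, 0.5], v_d ∈ [0, 10] mm/s, S0 ∈ (0, 10 × max signal].
  The D* lower bound of 5 µm²/ms reproduces the floor behavior seen in
  practice where voxelwise D* estimates pile up at the bound; it is
  configurable. Initialization is segmented (log-linear fit on b ≥ 200 for
  D and intercept; D* starts at 10). The ballistic fit additionally
  multi-starts over a small (f, v_d) grid: at f = 0 the v_d gradient
  vanishes, and a single bad start can strand the optimizer at the v_d
  bound; the lowest-deviance start wins. Non-converged voxels become NA
  sentinels and are excluded from ROI statistics.
* `residual_map()` is the per-voxel RMS difference between the fitted
  signal representation and the averaged data — near zero for
  self-consistent data, and systematically inflated by uncorrected drift
  (most visibly for the rigid ballistic model in the strong-drift ROI).

## Drift metrics and statistics

`drift_first_last()` is the simple metric: ROI-median signal change between
a scan's first and last b = 0 acquisition, normalized per 5 minutes.
`drift_slope()` fits the ROI-median signal against time with one intercept
per encoding direction and a common slope (fixed per-direction intercepts
in place of a random intercept — the slope point estimate is identical
under the balanced designs used here, and it avoids a mixed-model
dependency), reporting the slope as % of the mean intercept per 5 min.

`friedman_exact()` uses the rank statistic
$\chi^2_F = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ with average ranks
for ties, and computes the permutation p-value over all $(k!)^n$
within-block assignments *exactly*: for $k \le 3$ by convolution over
blocks (identical to enumeration, polynomial in $n$), for larger $k$ by
direct enumeration under a configurable cap with a chi-square fallback.
Worth knowing: on null data at $n = 20, k = 3$ the exact and chi-square
p-values can differ by ~0.03–0.07 in the mid-range (the permutation
distribution is discrete); in the decision-relevant region (p < 0.2) they
agree within 0.02. `signed_rank_exact()` computes the two-sided exact
Wilcoxon signed-rank p by dynamic programming over sign flips (identical
to $2^n$ enumeration; zero differences dropped, average ranks on ties),
with a tie-corrected normal approximation beyond n = 25. The convention
mirrors the gate-then-pairwise scheme: a Friedman p < 0.05 licenses
pairwise signed-rank tests at 0.05.

`select_representative()` identifies "typical" example data: rank every
observation's distance from its (ROI, scan) column median, sum ranks per
(subject, repetition), return the minimizer.

## Problem sizes and reproducibility

The test and acceptance simulations use phantoms of 16×16×8–32×32×8 voxels,
truth grids of 20 points spanning the phantom ranges, 500-voxel noise
panels at SNR 100, and 10 seeded phantoms for the order-effect sign test —
sizes chosen so the full chain (drift fit included) is exercised end to end
while the whole suite runs in well under a minute of fitting time per
criterion. Every random draw flows from an explicit seed argument
(`make_phantom`, `add_noise`, `run_pipeline` config); two runs of the same
configuration are byte-identical.

## Known limitations

* Drift outside the second-order space–time family (e.g. per-slice or
  abrupt drift) is not representable; corrections can only project onto
  the family.
* The temporal model uses acquisition index, so variable volume timing
  would need resampling.
* The segmented sIVIM estimator's bias on biexponential signals is
  inherent to the three-point design, not a fitting artifact.
* The ballistic preset's c-values are synthetic; quantitative v_d from real
  scans requires the true flow-encoding factors.
* `fit_diffusive`/`fit_ballistic` fit voxels independently; no spatial
  regularization or Bayesian shrinkage is provided.
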