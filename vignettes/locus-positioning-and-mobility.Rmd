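---
title: "Measuring subnuclear locus position and mobility with nucperi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subnuclear locus position and mobility with nucperi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucperi)
```

## What the package measures

A yeast nucleus in G1 is roughly a 2 um sphere. A chromosomal locus tagged
with an operator array and a fluorescent repressor appears as a single
diffraction-limited focus; a nucleoporin-GFP fusion draws the nuclear
envelope as a thin bright shell. From a two-channel z-stack the package
answers two questions per cell: how far the focus is from the envelope
(the positioning assay), and — from a time-lapse of such stacks — how much
nuclear space the locus explores (the mobility assay). Both are compared
between strains or conditions with the assay's standard statistics.

All coordinates are physical, in um, axis order (z, y, x), with voxel
centers at `(i - 0.5) * pitch`. Thresholds are in physical units so a
pitch change never silently changes behavior.

## The positioning assay

**Envelope segmentation.** The rim signal is a shell, so each z-slice that
carries strong signal is probed with rays from a robust center estimate
(intensity-weighted centroid of above-median signal). Along each ray the
ridge — the intensity maximum, refined by quadratic interpolation — marks
where the slice crosses the envelope. The resulting boundary point cloud
is fit with a general ellipsoid (algebraic least squares on the quadric
`x'Mx + b'x = 1`, then iteratively reweighted with Tukey biweights so
stray ridge points do not drag the surface). The fit residual (RMS
approximate geometric distance) is reported; segmentations with fewer
than 30 ridge points or residuals above 0.25 um raise a
`poor_envelope_fit` condition rather than returning a bad surface.

**Convention: the ridge mid-line.** The measured distance is taken to the
fitted mid-line of the shell signal, not to its inner or outer edge. The
shell's apparent thickness is dominated by optical blur, and the original
assay software does not document which edge it used; the mid-line is the
symmetric, reproducible choice, and it is applied identically to every
cell and condition, so between-group comparisons are unaffected by the
convention.

**Focus localization.** Difference-of-Gaussians responses at 0.8x, 1x and
1.25x the configured PSF sigma are combined by voxelwise maximum;
candidate peaks are 26-neighborhood local maxima above a robust threshold
(median + 5 MAD of the response). The brightest candidate wins and is
refined to subvoxel precision by an intensity-weighted centroid over the
background-subtracted 3x3x3 neighborhood. When several candidates pass,
the count is reported (`n_candidates`) so multi-focus cells can be
flagged; when none passes, the cell is flagged `no_focus` — a position is
never fabricated. The quality score `snr/(snr + 5)` is monotone in peak
SNR and lies in [0, 1).

**Distance.** For a focus strictly inside the fitted ellipsoid the
shortest distance to the surface is found from the Lagrange stationarity
condition, whose parameter is bracketed in `(-min(a)^2, 0)` and solved by
`uniroot` to 1e-12 um; focus coordinates exactly on a principal plane are
perturbed by 1e-12 um so the bracket is valid (the induced error is
negligible). Foci numerically outside the surface — segmentation error,
not biology — are clipped to distance 0 and flagged
`focus_outside_surface` rather than dropped, keeping QC auditable.

**2D middle-section mode.** For regular nuclei the assay tradition
measures in 2D on a maximum-intensity projection of a few middle
sections. `distance_to_periphery_2d()` pins "a few" to a configurable
`k_mid` (default 3, within the two-to-four-section display convention),
extracts the projected rim contour by the same radial ridge detection,
and returns the in-plane distance to the contour polyline. The package
never auto-selects between 2D and 3D — which mode matches which strain
morphology is a scientific judgment, so the caller chooses.

## The mobility assay

**Trajectories.** One focus per nucleus makes linking trivial: per-frame
detections become a time-ordered track, failed frames become gaps, and
every displacement pair spanning a gap is excluded. Note that a single
missing frame removes *both* lag-1 pairs that touch it. Whole-nucleus
motion is removed by subtracting the per-frame envelope-channel centroid;
the total centroid path length is attached as a stationarity score so the
"nearly stationary nuclei" selection of the classical protocol can be
applied as an explicit, logged filter instead of a manual choice.

**MSD.** Each cell's time-averaged MSD uses all overlapping valid pairs
at each lag; the ensemble curve is the unweighted mean across cells with
the standard error across cells as its uncertainty (matching error bars
that represent SEM over >= 20 cells). Lags run to half the shortest track
— the standard practice bound on estimator variance. A pooled-pair
weighting is deliberately not the default: it would overweight long
tracks.

**Plateau, Rc, volume.** The plateau is estimated by fitting the
saturating form `MSD(tau) = P (1 - exp(-tau/tau_c))`; the fit is declared
non-converged when `tau_c` exceeds a third of the lag window (the curve
is still rising — e.g. free diffusion) or the optimizer fails, in which
case the mean of the last third of lags is the documented fallback. The
radius of constraint uses the uniform-ball convention: for two
independent uniform points in a ball of radius R, `E|X - Y|^2 = 6R^2/5`,
so `Rc = sqrt(5P/6)` in 3D (`sqrt(P)` in 2D from the disc analogue). The
prior literature derives Rc "as previously described" without printing a
formula, so the convention here is stated, not inferred; it is a config
switch (`convention`) so an alternative spring-confinement variant can be
selected for cross-comparison. The explored volume is `V = (4/3) pi Rc^3`
exactly, and volume fold changes equal the cube of the Rc ratio by
construction.

**Group comparison.** The per-cell statistic is the plateau of each
cell's own time-averaged MSD (tail-mean fallback when its fit does not
converge), compared by the two-tailed Mann-Whitney test; the group-level
summaries (ensemble plateau, Rc, V, volume fold) are reported alongside.

## The statistics module

The two-sample z-test is the unpooled (Welch-style) statistic on means
with sample variances — the natural reading for the assay's large
per-group cell counts; a pooled option exists. Whether the original test
was on means or on proportions beyond a distance threshold is not
documented; means were chosen as the standard interpretation. Quartiles
use linear interpolation between order statistics (R type 7), again
configurable because plotting software conventions differ. The
Mann-Whitney U uses midranks; the exact two-tailed p comes from the full
permutation null (computed via the exact U distribution) when both groups
have at most 12 observations and no ties, otherwise a tie-corrected
normal approximation with continuity correction. No multiple-testing
correction is applied by default, matching the per-figure pairwise
reporting convention; Bonferroni/BH are available for batch reports.

## The synthetic-data generator

The generator emulates the assay's two imaging regimes: stills of 28
z-sections at 0.25 um spacing, and time-lapses of 20 z-sections at 0.30
um spacing imaged every 12 s for 5 min (26 frames). The in-plane pixel
pitch, never stated alongside those section spacings, defaults to 0.1 um
— a typical wide-field camera pixel at 100x magnification.

* **Envelope**: a Gaussian radial profile around the ellipsoid surface
  (FWHM `shell_thickness`, default 0.25 um), representing the optically
  blurred rim directly; no further PSF convolution is applied to it.
* **Focus**: a separable anisotropic Gaussian PSF, default sigma
  (0.35, 0.13, 0.13) um (z, y, x) — a standard wide-field approximation;
  a full vectorial optical model is out of scope.
* **Noise**: Poisson shot noise on signal plus background, then additive
  Gaussian read noise; both can be disabled for oracle tests. SNR is
  controlled exactly: peak 35 photons over background 10 with read noise
  sd 2 gives `35/sqrt(35 + 10 + 4) = 5`.
* **Placement laws**: the localization literature calls a distribution
  "peripheral" without stating one, so the generator offers explicit
  laws instead of inferring: `uniform` in the nuclear volume, or
  `peripheral` with depth below the surface drawn from an exponential
  (mean 0.1 um, truncated to the interior).
* **Motion**: discrete Brownian steps (per-axis variance `2 D dt`)
  confined to a reflecting sphere. Overshoots are reflected specularly
  across the boundary (radially: `r -> 2R - r`), which is only valid for
  steps small against R; the guard `D dt <= (R/5)^2` is enforced on the
  internal step. When the *frame* interval violates the guard — as the
  study regime D = 0.005 um^2/s, dt = 12 s, R = 0.5 um does — each frame
  is subdivided into the smallest number of sub-steps restoring validity
  and positions are recorded at the frame interval. An explicitly forced
  coarser stepping is refused with an error. The optional peripheral
  tether applies a harmonic restoring displacement `-k (d - d0) dt`
  toward a shell at depth `d0`; the stiffness k is expressed per unit
  time (s^-1) so the term is invariant under sub-stepping.
* **Determinism**: every simulation consumes one named seed;
  population-level datasets derive per-cell seeds from the master seed by
  a fixed integer hash kept below 2^31. Identical config and seed
  reproduce every voxel and trajectory point exactly.

What the generator does *not* emulate — deconvolution artifacts,
photobleaching, camera gain structure, multi-nucleus fields, irregular
(non-ellipsoidal) nuclear shapes, chromatin-polymer correlations in the
motion — bounds what passing tests show: they validate the measurement
chain against known geometry and known diffusion, not the biology of any
particular strain.

## Numerical choices and problem sizes

Storage is multi-page 32-bit TIFF; the codec stores fixed-point samples,
so written intensities are quantized at ~2.4e-10 of full scale
(`tiff_quantization()` reproduces the stored grid bit-exactly; the error
is ten orders of magnitude below photon noise). Validation uses problem
sizes at which the relevant estimators stabilize: 50 random nuclei for
the distance-oracle sweep, 200 cells for low-SNR localization, 100 tracks
of 26 frames for confinement-radius recovery (the study's own per-group
scale is >= 20 cells), 2000 replicates for test calibration. The
uniform-ball equilibrium check uses a long single track with fine steps
(0.25 s) because the reflected walk's stationary distribution approaches
uniform only as the step size shrinks; at the coarse imaging step the
equilibrium is biased slightly inward, which is a property of the scheme,
not an estimator error.

## Known limitations

* The ellipsoid is the only surface model; strongly irregular mutant
  nuclei violate it, and the fit residual plus `poor_envelope_fit` flag
  are the guard, not a fix.
* The 2D contour mode assumes the projected rim is star-shaped around
  the center estimate (true for convex nuclei).
* Sub-voxel localization by 3x3x3 centroid saturates around a tenth of
  a pitch of bias for foci near voxel boundaries; this is well inside
  the assay's half-pitch accuracy requirement but matters if pitches
  grow.
* The confined-diffusion model is a hard reflecting sphere; polymer
  dynamics, viscoelastic memory and anomalous exponents are out of
  scope, and the MSD module deliberately fits no anomalous-diffusion
  exponent.
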