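---
title: "Astigmatic traction force microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Astigmatic traction force microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atfm)
```

Traction force microscopy (TFM) infers the stresses a cell exerts on its
substrate from the displacements of fiducial marker beads embedded in an
elastic gel. Classical TFM measures lateral displacements only; the
astigmatic variant (aTFM) implemented here adds the axial dimension from a
*single* camera frame: a cylindrical lens reshapes the microscope PSF so
that its two orthogonal widths encode the emitter's position relative to
the focal plane, giving 2.5D measurements — lateral *and* normal surface
displacement, hence shear (S~x~, S~y~) and normal (S~z~) surface stresses
— at single-frame temporal resolution. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic
validation does and does not establish.

## The PSF model and 3D localization

**Empirical spline PSF.** The axial encoding is calibrated from a z-stack
of sparse beads (2 µm range, 10 nm steps by default). Each detected bead
is aligned to the ensemble mean — intensity centroid first, then
a gradient-based (Lucas–Kanade) sub-pixel refinement, iterated three
times — and averaged. The averaged template is normalised to unit sum per
z-slice and interpolated with cubic splines: an "fmm" (not-a-knot style)
cubic along z at every sample of a 2× laterally oversampled template, with
C¹ Catmull–Rom interpolation laterally. Knot spacing equals the
calibration step (10 nm) in z and half a pixel laterally. The stored model
maps an emitter offset (dx, dy, z) to expected photons per pixel; a model
built from noiseless renderings of known width curves reproduces them to
< 0.4% of peak across z ∈ [−800, 800] nm.

**Sign convention.** z > 0 means the bead lies above the focal plane and
the PSF elongates along x. The synthetic generator
(`gaussian_defocus_curves`, focal offsets ∓250 nm, depth of focus 400 nm,
in-focus width 130 nm at a 60.4 nm pixel) and the fitter share this
convention.

**Width measure.** The width–z lookup used to initialise the fit and to
derive the overlap-exclusion radius reports Gaussian-equivalent widths
from the FWHM of the patch marginals rather than raw second moments: raw
moments saturate when the defocused tails leave the analysis window,
which would destroy the strict monotonicity of
w~x~(z) − w~y~(z) — the property that makes z decodable — beyond
|z| ≈ 500 nm.

**MLE fitting.** Each candidate window (default 13 px) is fitted with
`photons · PSF(dx, dy, z) + background` under a Poisson pixel-noise
model — the correct likelihood in the low-count regime — by damped Newton
(Levenberg-type Fisher scoring) iterations over the five parameters, with
analytic PSF derivatives, at most 50 iterations and a 0.01 nm position
tolerance (10⁻⁴ of the ~100 nm parameter scale). Only converged fits are
kept. Candidate detection runs on a 3×3-smoothed image and collapses
duplicate maxima closer than 3 px: Poisson noise on a ~2-px-wide peak
frequently creates twin maxima, and without the collapse a bead
stochastically disappears from individual frames, destroying trajectory
completeness. Maxima closer than the candidate separation (default 7 px)
are removed symmetrically; at the fitted-position level, localizations
with a same-frame neighbour within the exclusion radius (default twice
the largest PSF width at |z| = 800 nm, ≈ 730 nm) are removed
symmetrically as well.

**Uncertainty.** `crlb()` computes Cramér–Rao bounds from the Fisher
information of the Poisson model with all five parameters free. The
Monte-Carlo efficiency of the fitter is 1.03–1.08× the bound at the
default photon budget. Note the photon-doubling behaviour: with the
background held fixed, doubling the signal improves every bound by
slightly *more* than 1/√2, approaching 1/√2 exactly as the background
vanishes.

## Trajectories and displacement fields

Localizations are linked frame-to-frame by greedy nearest-neighbour
assignment in 3D with a distance gate (default 500 nm; adequate at
0.3 beads/µm² and ≤150 nm/frame motion — a global assignment would add
cost without benefit at this density). Only beads present in every frame
enter displacement fields. Rigid 3D drift is estimated as the mean
displacement of reference beads (user-supplied, or automatically the
lowest decile of total motion, standing in for "far from the cell
contact") and subtracted; by construction the reference ensemble is
static afterwards. Trajectories are smoothed with a width-10 temporal
median (centred, truncated at the ends; clamped for shorter
trajectories), then bead displacements relative to frame 0 are
interpolated onto a regular grid — piecewise-linear on the Delaunay
triangulation of the frame-0 positions, grid points outside the convex
hull marked invalid — and median-filtered per component with a width-10
window: 604 nm at the 60.4 nm pixel. Temporal filtering precedes
gridding; spatial filtering follows it. The interpolation kernel and the
per-component (rather than on-magnitude) spatial median are the
documented choices where several options would be defensible.

## From displacements to stresses

The substrate is modelled as a linear-elastic, nearly incompressible
(ν = 0.495) half-space: the gels are thick compared to the displacement
decay length, which is exactly the regime in which the half-space surface
Green's tensor (Boussinesq for normal, Cerruti for tangential loads)
governs the surface response, so the displacement→stress map is a
(de)convolution evaluated spectrally. Rather than the analytic k-space
tensor, the kernels are the FFT of the *sampled* real-space tensor with
an analytic cell integral at the singular cell (the mean of 1/r over a
centred square of side h is 4·asinh(1)/h): this makes the forward
response to a point load exact (the Boussinesq
u~z~ = P(1−ν²)/(πEr) is reproduced to <0.1% off-centre) and makes
forward and inverse maps exactly mutually inverse on the padded grid.
The normal/tangential coupling terms, proportional to (1−2ν), are
retained; at ν → 0.5 they vanish and the solver reduces to the familiar
decoupled forms.

Before inversion the mean displacement is subtracted per component (the
rigid-body mode carries no strain and is unobservable), invalid grid
points are zero-filled, a 10% Tukey taper is applied at the borders, and
the grid is zero-padded 2×. The k = 0 mode of the recovered traction is
set to zero. Zeroth-order Tikhonov damping is available
(`regularization`, scaled by the peak kernel magnitude) but defaults to
0: the median-filtered input is already band-limited.

**Force balance matters.** Validation tractions are force-balanced
(dipole-like), as cell tractions must be: an unbalanced pattern has net
force and hence 1/r displacement tails that no finite field of view
captures, so its inverse-consistency error is dominated by window
truncation (tens of percent) for *any* method. With balanced Gaussian
spots (σ = 1 µm, 500 Pa shear / 300 Pa / 150 Pa normal peaks, 25.6 µm
grid at 100 nm) the forward–inverse roundtrip error is 4.3% in relative
L2 over the whole field and <1% in the interior.

**Subsurface stress.** The traction components on horizontal planes at
depth d (σ~zx~, σ~zy~, σ~zz~) follow from the surface traction by
analytic, ν-independent propagators (e.g. (1+kd)e^(−kd) for normal→normal);
depth 0 reproduces the surface field identically and the cross-sections
decay into the bulk.

**Stress-uncertainty budget.** `propagate_noise()` draws i.i.d. Gaussian
displacement noise per grid point at the measured localization
uncertainties and passes it through the *full* filtering chain — the
width-10 temporal median (≈0.40 attenuation), the 604 nm spatial
median — and the inversion, reporting per-point stress SDs over the
interior (the tapered border excluded). The measured uncertainties are
raw per-frame values while stress maps are computed from filtered fields,
so the chain must include both filters. For (9, 9, 22) nm on a 10 kPa gel
at 60.4 nm grid spacing this gives ≈31 Pa lateral and ≈92 Pa normal —
the same order as the published budget; the exact value depends strongly
on the discretisation of the displacement-to-stress map, which is why the
acceptance check is an order-of-magnitude (factor 2.5) one.

## The static-load calibration

A sphere of known weight resting on a soft gel provides an absolute force
reference. The buoyancy-corrected load of a 70 µm silica sphere
(2.65 g/cm³) in aqueous buffer is F = (π/6)d³(ρ~s~−ρ~m~)g = 2.91 nN;
buoyancy correction is the default (and matches both the nominal and the
fitted values). The indented surface spans ~3 µm axially — beyond the
single-frame astigmatic range — so it is reconstructed by stitching a
100 nm piezo scan: per slice, beads are localized, kept while inside the
reliable range (|z| ≤ 700 nm), clustered laterally (500 nm gate) and
averaged with inverse-CRLB-variance weights. Clusters seen in fewer than
two slices are discarded as spurious (a real bead appears in ~14
consecutive slices).

The radial profile is built about the contact centre (least-squares
paraboloid on the deepest 35% of points — exact on the Hertzian cap,
which is quadratic inside the contact), with 500 nm bins. The undeformed
height is estimated from the outer 15% of radii and refined, twice, against
the fitted model's own far-field tail: the Hertzian far field decays only
like 1/r, so a naive "flat far field" baseline would bias the load by
several percent at realistic field sizes. The two-branch model (linear in
the load P, with contact radius a) is then fitted by Levenberg–Marquardt
least squares with the gel modulus E held fixed — P and E are exactly
degenerate if both float. The synthetic ground truth uses a = 3 µm,
consistent with the observed ~3 µm indentation depth; note this is
treated as a free geometric parameter of the profile, not derived from
sphere elasticity.

## The synthetic generator

`synthetic_scene()` emulates the study conditions: 0.3 beads/µm² layouts
(uniform, thinned to 1 µm minimum separation), 100-frame time series at
1 s, a 60.4 nm pixel, and two background conditions — 2 photons/pixel
(minimal) and 20 photons/pixel modulated by a smooth seeded low-pass
random field (fluorescent bleed-through of a labelled cell; only its
statistical effect on fitting matters, so no cell morphology is
rendered). The 5000-photon budget is a stand-in chosen so that measured
localization uncertainties land in the few-nanometre lateral /
several-nanometre axial regime typical of astigmatic imaging; the source
acquisition's photon counts are not public, so the printed 4/7 nm and
9/22 nm figures are validated as orderings (high noise strictly inflates
all axes, axial exceeds lateral), not as absolute numbers. Ground-truth
displacement generators: `static`, `rigid_drift` (default (5, −3, 2)
nm/frame), `hertz_indentation` (the calibration bowl), and
`traction_spots` — force-balanced Gaussian spots on a 10 kPa gel whose
displacement field (computed with the package's own forward solver) ramps
linearly over the movie, with amplitudes inside the observed ranges
(~60 nm axial, ~200 nm lateral). Everything is deterministic given the
scene seed, and rendering is bit-identical across runs.

What passing these tests shows: the estimator chain is consistent and
efficient *under its own model* — elliptical-Gaussian-like PSFs, Poisson
noise, ideal linking, a truly semi-infinite linear substrate. What they
do not show: robustness to PSF aberrations beyond astigmatism,
camera-specific (sCMOS) noise, bead detachment or photobleaching,
finite gel thickness, or nonlinear gel response under the indenter.

## Problem sizes and runtimes

The test-suite scenes are scaled for desk use: 8–16 µm fields (20–80
beads), 4–40 frames for pipeline runs, a 24×24 µm field with a 37-slice
piezo scan for the imaging calibration, 250 Monte-Carlo fits for the
efficiency check, 256² grids for the inversion benchmarks, and 60
repetitions for the stress-noise budget. The acceptance script's
calibration uses the full 40×40 µm field over 12 seeds. The native
(Rcpp) fitter localises a bead in ~1.4 ms, so the complete suite runs in
about a minute.

## Known limitations

* Semi-infinite substrate: no finite-thickness correction; thin gels on
  glass will read biased stresses.
* Single-emitter fitting only; overlapping beads are rejected, not
  jointly fitted, so usable bead density is bounded (~0.3/µm²).
* Greedy linking without gap closing: a single missed frame removes a
  bead from the analysis (by design — only complete trajectories enter
  fields).
* The Hertz fit assumes frictionless, adhesionless (non-JKR) contact and
  a linear gel.
* The inversion recovers tractions only up to the rigid-body mode and
  only inside the bead convex hull; net force over the field is
  implicitly zero.
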