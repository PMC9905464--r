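---
title: "Motion-compensated SPECT reconstruction and voxel dosimetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-compensated SPECT reconstruction and voxel dosimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mocodose)
```

# The problem

Selective internal radiation therapy (SIRT) delivers ⁹⁰Y microspheres to
liver tumors through the hepatic artery. Planning relies on a ⁹⁹ᵐTc-MAA
SPECT/CT scan whose biodistribution is assumed to mimic the microspheres:
from it the planner derives per-organ absorbed doses, the lung shunt
fraction (LSF), the tumor-to-normal-liver ratio (TN), and the activity to
inject. A SPECT acquisition takes ~25 minutes, so the liver — which moves
about a centimeter with every breath — is imaged smeared. `mocodose`
provides a fully synthetic laboratory for quantifying what that smear does
to the planning numbers, and what a data-driven motion-compensated
reconstruction recovers: a 4D digital phantom, a list-mode SPECT simulator,
conventional (3D) and motion-compensated (3Dcomp) OSEM reconstruction,
threshold/Boolean VOI construction, voxel dosimetry, and the comparison
statistics, end to end under one seed.

Because everything is synthetic, per-VOI ground-truth doses exist; all
claims about reconstruction accuracy in the test suite are made against
that ground truth, never against the clinical numbers the package cannot
reproduce without patient data.

# The phantom and its stated world

`phantom_spec()` describes a soft-tissue body, two lungs, a liver and 1–3
spherical lesions as axis-aligned ellipsoids whose geometry is expressed as
fractions of the grid extent, so the identical anatomy rasterizes at the
desk grid (32³ × 4.418 mm) and the acquisition grid (128³ × 4.41806 mm).
Label codes are 0 air, 1 body, 2 lung, 3 liver, 10+t lesion t; attenuation
at 140.5 keV is class-based (air 0, lung 0.004 /mm, soft tissue 0.015 /mm,
liver 0.0158 /mm). The liver receives its own, slightly higher attenuation
class so that the attenuation map — the package's CT stand-in — actually
encodes where the liver is; without it the automated reference-phase
selection would have no anatomical signal to match against (a real CT shows
the liver; a three-class attenuation map would not).

Breathing is a rigid, voxel-quantized translation of the moving-organ
complex with a cosine waveform and an end-exhale dwell: phase *p* of *n* is
displaced by `-amplitude * (1 - cos(2*pi*p/n))/2`, so phase 0 is end-exhale
with the liver at its most cranial position and the motion is
caudal/posterior (default direction ∝ (0, 0.4, 0.9), the cohort-mean AP/CC
mix). Cohort amplitudes are drawn from a truncated normal (mean 9.5 mm, sd
2.7 mm, range 3.4–16.8 mm), matching the clinical distribution the package
emulates; tumor volumes are log-uniform (2–200 mL at full scale, 2–15 mL at
desk scale where the half-size liver cannot hold larger spheres, with radii
capped at 85% of the smallest liver semiaxis).

Two choices deserve emphasis:

* **Diaphragm-coupled lungs.** The lungs translate rigidly with the liver.
  With static lungs the lung-dose comparison is structurally one-sided:
  the uncorrected reconstruction can only *gain* lung-mask counts (liver
  smear) and the compensated one can only *lose* them (the liver-driven
  affine drags static lung counts out of the mask), which forecloses the
  restoration mechanism by which compensation can raise lung dose in
  patients. Coupled motion is also closer to diaphragm physiology.
  `phantom_spec(moving_organs = "liver")` restores the static variant.
* **Centered phase dwell intervals.** Phase *p* occupies
  `[(p-1/2), (p+1/2)) * T/n` of each cycle, so the displacement assigned to
  phase *p* is the waveform value at the *center* of its dwell interval.
  With start-aligned intervals the piecewise-constant position waveform is
  systematically delayed by half a phase relative to the label grid, and
  any phase-estimation method appears to have a built-in half-phase error
  it does not actually have.

Total activity is conserved exactly across phases (the complex is moved by
integer voxel shifts, ties broken toward the lower index; vacated voxels
revert to body background), and lung activity is set so the lung share of
liver+lung activity equals the configured shunt fraction exactly.

# Acquisition model

`acquisition_spec()` defaults to the clinical protocol: 60 step-and-shoot
projections over 360°, 25 s each, 128² bins of 4.418 mm, a primary window
at 140.5 keV and a scatter window at 120 keV. The "± 20%"/"± 5%" vendor
nomenclature is read as *total* window width equal to 20%/10% of the window
center (126.45–154.55 keV and 114–126 keV); this is the conventional
reading but is config-overridable. The projector is parallel-beam with one
detector bin per voxel column: line integrals of activity attenuated by
`exp(-∫μ)` toward the detector, convolved per depth plane with a Gaussian
PSF whose FWHM grows linearly with distance (intercept + 0.044 mm/mm,
pinned to 7.4 mm at 100 mm — the LEHR resolution figure). The
backprojector is the algebraic transpose of the forward projector (same
bilinear rotation weights, same attenuation factors, same symmetric
normalized kernels), which the test suite verifies against a brute-force
matrix construction on an 8³ grid.

Scatter is a kernel surrogate, not physics: the unattenuated projection
blurred by a broad Gaussian (FWHM 40 mm) feeds the scatter window (fraction
0.3) and contaminates the primary window (fraction 0.3). Its only purpose
is to exercise the dual-energy-window (DEW) correction path, which
estimates primary-window scatter as `k ×` scatter-window counts with the
Jaszczak convention `k = (primary width / scatter width)/2 ≈ 1.171`,
clipped at the observed primary counts.

List-mode events are generated by partitioning each projection's dwell
among phases, Poisson-sampling the per-phase expected projections, and
time-stamping each count uniformly within its phase's dwell intervals. The
simulator stores each event's true phase, which the gating tests use as
ground truth.

# Data-driven gating

The respiratory signal is extracted with Laplacian eigenmaps: events are
rebinned into 0.5 s time bins histogrammed on a coarse 16×16 detector grid;
rows are normalized to unit sum and centered per projection; a
Gaussian-kernel k-NN graph (k = 20, bandwidth = median k-NN distance) is
built, and the first nontrivial eigenvector of the normalized graph
Laplacian is the 1D signal, sign-fixed against the axial count-centroid
surrogate. Two numerical lessons are baked into the defaults:

* temporal smoothing of the *features* is off by default — it makes graph
  neighbors temporally adjacent rather than phase-similar, and the leading
  eigenvector then orders time, not respiratory phase;
* cycle boundaries come from interpolated (sub-bin) zero crossings, then a
  single global offset aligns them with the signal *extremum* (end-exhale),
  estimated from the phase of the signal's fundamental frequency
  component. Bin-quantized crossings carry a constant phase offset whenever
  `dt` divides the breathing period, and per-cycle peak picking is
  unreliable on the flat-topped exhale-dwell waveform; the global
  fundamental fit avoids both.

Phases are equal-time bins within each detected cycle (8 by default), and
events are labeled from their exact timestamps. The reference phase — selected
visually against the CT in clinical practice — is chosen
deterministically as the gated reconstruction maximizing the normalized
cross-correlation with the liver class of the attenuation map, ties to the
lowest index.

# Reconstruction

`osem()` is a standard multiplicative OSEM (default 15 subsets × 15
iterations, read as 15 full iterations each cycling all 15 subsets) with
attenuation, PSF and the additive DEW scatter estimate in the forward
model, no post-filtering, and zero-sensitivity voxels excluded. The
motion-compensated arm (`reconstruct_3dcomp()`) estimates, per phase and
per projection angle, a 6-parameter 2D affine mapping that phase's gated
projection onto the reference phase's (MSE on count-normalized, smoothed
projections; translation initialized at the centroid difference), applies
the inverse mapping to each event's detector coordinates, splats the
corrected events bilinearly and reconstructs from all counts — so its
noise level matches the conventional 3D reconstruction.

Per-angle affine fits on gated projections (1/8 of the counts) are noisy,
and that noise acts as a blur on the corrected events which biases small
structures low. Since the true transforms vary smoothly with angle, the
fitted parameters are smoothed across angles with a circular moving average
(window 5) by default; the zero-motion null (per-VOI |PDD| inside the
Poisson-scale 5% tolerance the acceptance suite asserts) degrades markedly
with the smoothing off.

# Dosimetry

The Monte Carlo engine of the source study is deliberately replaced by two
deterministic engines (`dose_rate()`): *local deposition* (each decay's
mean beta energy, 0.9337 MeV, deposited in its own voxel) and a *dose-point
kernel convolution*. The packaged radial kernel is **synthetic**: an
exponential energy-density profile (fall-off 2.2 mm, truncated at 11 mm)
normalized so the deposited energy integrates exactly to one decay's mean
beta energy — it reproduces the correct total energy and the
charged-particle-equilibrium limit (kernel = local in uniform regions,
verified to 2%), but it is not a published ⁹⁰Y kernel and absolute
near-field dose gradients should not be quoted from it. Calibration scales
the reconstruction so liver+lung counts equal the injected activity; decay
integration multiplies the initial dose rate by `T½/ln 2` with the planning
half-life of 64 h exactly. The prescription converts the perfused-liver
dose per unit activity into an activity for a configured prescription dose
(120 Gy by default in the pipeline config; ratios between arms are
independent of the value).

# VOIs and metrics

The seven VOIs follow the planning set algebra exactly: perfused liver (PL)
is the ≥5%-of-liver-maximum threshold of the reconstruction intersected
with the liver (threshold inclusive; the source does not state strictness);
HL = liver − tumors; HPL = PL − tumors; HR = liver − PL − tumors;
liver/lung overlap voxels go to the liver before any derived mask is
computed. PL is computed per reconstruction arm.

Amplitude estimation registers the exhale and inhale gated reconstructions
restricted to the dilated liver mask, translation-only, maximizing
32-bin-histogram mutual information; the amplitude is the norm of the
translation, and masks below 30 voxels return an explicit not-estimable
result (the clinical "too small to register" case).

Of the seven per-lesion predictors, two needed interpretation. The border
distance map (features 2–3) is evaluated on the *lesion border* voxels
(min/mean distance to the liver border), which makes the degenerate
lesion = liver case zero. The center-of-mass distance (features 6–7) is
implemented literally — distance from the lesion COM to the liver border
(50 mm for a 10 mm sphere centered in a 50 mm liver, not 40 mm) — because
the alternative margin-style reading duplicates feature 2. Feature 4 is the
CC gap between the most cranial lesion voxel and the most cranial liver
voxel within the lesion's axial footprint (`cc_gap = "global"` switches to
the whole-liver top).

The statistics follow the planning protocol: Shapiro–Wilk on each paired
series at α = 0.05, then a paired t test if both are normal, otherwise a
paired Wilcoxon (constant series force the Wilcoxon branch and are
flagged); Bland–Altman limits are mean ± 1.96 sd with the differences'
normality reported; Spearman correlations are reported with raw p-values
(an optional multiplicity correction exists but defaults off, mirroring the
protocol).

# What a green test does and does not establish

The generator emulates: cosine breathing with end-exhale dwell, rigid
translation, class-based attenuation, Poisson counting statistics,
depth-dependent resolution, and a kernel scatter surrogate. It does not
emulate: hysteresis or cycle-to-cycle variability, deformable motion (the
clinical observation that tumors move slightly more than livers is a
deformation effect a rigid model cannot show), septal penetration or dead
time, CT contouring error, or real scatter physics. Green tests therefore
establish internal correctness (projector adjointness, OSEM convergence,
count bookkeeping, formula exactness) and *direction/ordering* claims under
the stated world (compensation recovers tumor dose; smaller lesions suffer
larger errors), not clinical effect sizes.

One acceptance expectation is knowingly red: the source study's positive
median lung-dose difference (3Dcomp above 3D, +6.4%). With ground-truth
contours the synthetic world robustly yields the *opposite* sign, because
the uncorrected 3D arm overestimates lung dose (hot liver smeared into a
tight lung contour at ~20× the lung's own shunt concentration) and the
compensated arm is nearly unbiased — compensation *improves* lung
dosimetry, lowering it. The study itself attributes its positive sign to
motion-artifact-enlarged CT liver contours absorbing the 3D smear, a
contouring-error mechanism the phantom deliberately does not model. The
expectation is asserted as specified and fails; the decisions ledger
carries the analysis.

# Numerical choices

* Rotation-based projector with bilinear interpolation; mass is conserved
  exactly at axis-aligned angles and to ~0.2% at oblique angles for
  activity inside the inscribed cylinder (the body always is).
* Gaussian kernels are truncated at 3σ and renormalized; symmetric kernels
  keep the projector pair exactly adjoint.
* Nearest-neighbor phantom shifts round half-voxels toward the lower index
  (deterministic ties).
* OSEM epsilon 1e-10 guards zero divisions; `0/0` ratios are 0.
* The desk preset (32³, 30 projections, 6 subsets × 5 iterations, ~4000
  detected events/s) runs a full patient in under a minute; the clinical-scale
  preset reproduces the acquisition protocol and is correspondingly slower.
* Seeds: every stochastic stage takes an explicit seed; a cohort is a pure
  function of (spec, master seed).
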