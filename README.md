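# mocodose

Respiratory motion blurs the ⁹⁹ᵐTc-MAA SPECT images used to plan ⁹⁰Y
radioembolization (SIRT) of liver tumors: the liver moves ~1 cm with each
breath while a projection integrates 25 s. `mocodose` is a fully synthetic
laboratory for measuring the dosimetric consequences and what a
motion-compensated reconstruction recovers. It chains, under one seed:

1. a 4D digital thorax phantom (liver, lungs, 1–3 tumors, configurable lung
   shunt) with cosine breathing and rigid, voxel-quantized translation;
2. a parallel-beam SPECT simulator — attenuation, depth-dependent Gaussian
   PSF (7.4 mm FWHM at 100 mm), a dual-energy-window scatter surrogate,
   Poisson list-mode events with timestamps and true phase labels;
3. data-driven respiratory gating: Laplacian-eigenmap signal extraction
   from the list-mode stream, 8-phase splitting, automated reference-phase
   selection against the attenuation map;
4. OSEM reconstruction (15 subsets × 15 iterations at full scale) in two
   arms from the *same* events: conventional `3D` and motion-compensated
   `3Dcomp` (per-phase, per-angle 2D affine correction applied to list-mode
   events, then one reconstruction from all counts);
5. the seven planning VOIs (liver, lungs, tumors, perfused liver PL,
   hepatic reserve HR, healthy perfused liver HPL, healthy liver HL) by
   5%-of-maximum thresholding and Boolean algebra;
6. voxel dosimetry: activity calibration on liver+lung counts, a ⁹⁰Y
   dose-point-kernel (synthetic, energy-conserving) or local-deposition
   engine, mono-exponential decay with a 64 h half-life;
7. the comparison layer: per-VOI percentage dose difference
   `PDD = (D_3Dcomp − D_3D)/D_3D × 100`, lung shunt fraction
   `LSF = C_lungs/(C_lungs + C_liver) × 100`, tumor-to-normal ratio
   `TN = (C_T/V_T)/(C_HL/V_HL)`, prescribed activity and its percentage
   difference (PDA), Bland–Altman agreement, breathing-amplitude estimation
   by mutual-information rigid registration, seven geometric tumor
   predictors, and the Shapiro–Wilk / paired t / Wilcoxon / Spearman
   protocol.

Because the phantom is synthetic, every quantity has a ground truth; the
package's claims are tested against it.

## Worked example

```r
library(mocodose)

cfg  <- run_config(preset = "desk", seed = 5)      # 32^3, 30 projections
spec <- base_phantom_spec(cfg)
spec$amplitude_mm <- c(0, 0, 10)                   # 10 mm cranio-caudal

rec <- run_patient(spec, cfg, patient_id = 1)
rec$doses[, c("voi", "dose_3d", "dose_3dcomp", "dose_true", "pdd")]
```

```
        voi dose_3d dose_3dcomp dose_true      pdd
1     liver  81.245       81.31    76.164  0.07523
2     lungs   4.786        4.64     4.461 -3.03493
3 tumor_any 210.754      223.77   267.408  6.17599
4        PL  81.245       81.31    76.164  0.07523
5        HR      NA          NA        NA       NA
6       HPL  79.235       79.09    73.195 -0.17668
7        HL  79.235       79.09    73.195 -0.17668
```

Reading the table: the tumor mean dose is 210.8 Gy in the uncorrected arm,
223.8 Gy with motion compensation and 267.4 Gy in ground truth —
compensation recovers about a quarter of the motion-induced tumor dose
loss at this lesion size (2 mL; the rest is partial-volume), while
liver-level doses barely move (|PDD| < 0.2%). HR is empty here (the whole
liver is perfused, so there is no hepatic reserve). The estimated breathing
amplitude is `rec$scalars$amplitude_est_mm` = 8.68 mm against a
voxel-quantized truth of 8.84 mm, and the reconstructed LSF (5.01% / 4.90%
for 3D / 3Dcomp) brackets the simulated 5% shunt. `run_cohort()` scales
this to a seeded cohort and adds the paired statistics and report figures;
`write_report()` persists CSV tables, a JSON summary and the figures.

Note one deliberate asymmetry with the clinical literature: with
ground-truth contours the lung PDD here is slightly *negative* (3D
overestimates lung dose via liver smear into the tight lung contour;
compensation fixes it), whereas the patient study this package emulates
reports a positive median driven by motion-artifact-enlarged CT liver
contours. See `vignettes/motion-compensated-dosimetry.Rmd` for the
analysis.

## Layout

- `R/` — phantom (`phantom_spec`, `generate_phase_set`, `sample_cohort`),
  simulator (`acquire_listmode`), gating (`laplacian_eigenmap_signal`,
  `assign_phases`), reconstruction (`osem`, `reconstruct_3d`,
  `reconstruct_3dcomp`), VOIs (`perfused_liver`, `derive_vois`), dosimetry
  (`calibrate_activity`, `dose_rate`, `integrate_decay`), metrics (`pdd`,
  `lsf`, `tn_ratio`, `pda`, `bland_altman`, `estimate_amplitude`,
  `tumor_features`, `stats_suite`), pipeline (`run_patient`, `run_cohort`).
- `src/` — the Rcpp projector core (rotation-based forward/back-projection,
  exact adjoint pair), event splatting, 3D translation, distances.
- `inst/extdata/y90_dpk_synthetic.csv` — the synthetic ⁹⁰Y radial kernel.
- `inst/cli/mocodose` — command-line entry (`simulate`, `run-all`).
- `vignettes/` — methods vignette (model, assumptions, design decisions,
  limitations).
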