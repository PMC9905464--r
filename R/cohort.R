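#' Full-study run configuration
#'
#' Bundles the phantom, acquisition, reconstruction, dose and analysis
#' settings behind one object with two scale presets. `"desk"` (default)
#' targets a single CPU: 32^3 grid, 30 projections, reduced OSEM iterations;
#' `"clinical"` mirrors the acquisition protocol (128^3 grid at 4.41806 mm, 60
#' projections, 15 subsets x 15 iterations) and is correspondingly slow.
#'
#' @param preset `"desk"` or `"clinical"`.
#' @param cohort_size number of synthetic patients.
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_phases respiratory phases for gating (default 8).
#' @param gating `"data-driven"` (Laplacian eigenmaps) or `"truth"` (use the
#'   simulator's phase labels; for ablation/speed).
#' @param injected_mbq injected 99mTc-MAA activity (default 243 MBq, the
#'   cohort mean).
#' @param prescription_gy prescribed dose to the perfused liver (no
#'   hard-coded clinical default is assumed downstream; 120 Gy here).
#' @param dose_engine `"kernel"` or `"local"`.
#' @param ct_phase 0-based true phase at which the attenuation map ("CT") is
#'   taken.
#' @param ... overrides for individual fields of the returned list.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "clinical"), cohort_size = 10L,
                       seed = 1L, n_phases = 8L,
                       gating = c("data-driven", "truth"),
                       injected_mbq = 243, prescription_gy = 120,
                       dose_engine = c("kernel", "local"), ct_phase = 2L,
                       ...) {
  preset <- match.arg(preset)
  gating <- match.arg(gating)
  dose_engine <- match.arg(dose_engine)
  cfg <- if (preset == "desk") {
    list(grid_shape = c(32L, 32L, 32L), spacing = rep(4.418, 3),
         n_projections = 30L, total_rate = 4000,
         recon = recon_config(n_subsets = 6L, n_iterations = 5L),
         gated_recon = recon_config(n_subsets = 6L, n_iterations = 3L),
         signal_dt = 0.5)
  } else {
    list(grid_shape = c(128L, 128L, 128L), spacing = rep(4.41806, 3),
         n_projections = 60L, total_rate = 20000,
         recon = recon_config(n_subsets = 15L, n_iterations = 15L),
         gated_recon = recon_config(n_subsets = 15L, n_iterations = 5L),
         signal_dt = 0.5)
  }
  cfg <- c(cfg, list(preset = preset, cohort_size = as.integer(cohort_size),
                     seed = as.integer(seed), n_phases = as.integer(n_phases),
                     gating = gating, injected_mbq = injected_mbq,
                     prescription_gy = prescription_gy,
                     dose_engine = dose_engine,
                     ct_phase = as.integer(ct_phase)))
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
base_phantom_spec <- function(cfg) {
  phantom_spec(grid_shape = cfg$grid_shape, spacing = cfg$spacing,
               total_rate = cfg$total_rate, seed = cfg$seed)
}

cfg_acquisition <- function(cfg, seed) {
  acquisition_spec(n_projections = cfg$n_projections, seed = seed)
}

voi_names <- c("liver", "lungs", "tumor_any", "PL", "HR", "HPL", "HL")

# per-arm analysis: VOIs, counts, calibration, dose, prescription
analyze_arm <- function(recon, masks, cfg, arm) {
  pl <- perfused_liver(recon, masks$liver)
  vois <- derive_vois(masks$liver, masks$lungs, masks$tumors, pl,
                      spacing = recon$spacing)
  counts <- vapply(voi_names, function(nm)
    if (any(vois[[nm]])) sum(recon$data[vois[[nm]]]) else NA_real_, 0)
  act <- calibrate_activity(recon, vois, cfg$injected_mbq * 1e6)
  dmap <- integrate_decay(dose_rate(act, cfg$dose_engine))
  doses <- vapply(voi_names, function(nm)
    if (any(vois[[nm]])) mean_dose(dmap, vois[[nm]]) else NA_real_, 0)
  vols <- vapply(voi_names, function(nm)
    sum(vois[[nm]]) * prod(recon$spacing) / 1000, 0)
  lsf_v <- lsf(counts[["lungs"]], counts[["liver"]])
  tn <- if (any(vois$tumor_any))
    tn_ratio(counts[["tumor_any"]], vols[["tumor_any"]],
             counts[["HL"]], vols[["HL"]]) else NA_real_
  # dose to PL per unit injected activity -> prescription
  dose_per_gbq <- doses[["PL"]] / (cfg$injected_mbq / 1000)
  a_gbq <- prescribe_activity(dose_per_gbq, cfg$prescription_gy)
  lesion_doses <- vapply(vois$tumors, function(tm)
    if (any(tm)) mean_dose(dmap, tm) else NA_real_, 0)
  list(arm = arm, vois = vois, counts = counts, doses = doses, vols = vols,
       lsf = lsf_v, tn = tn, activity_gbq = a_gbq, dose_map = dmap,
       lesion_doses = lesion_doses)
}

# ground-truth dosimetry from the phantom activity map at the CT phase
truth_arm <- function(phantom, masks, cfg) {
  act_true <- phantom$phases[[cfg$ct_phase + 1L]]$activity
  vois <- derive_vois(masks$liver, masks$lungs, masks$tumors,
                      pl = masks$liver, spacing = act_true$spacing)
  act <- calibrate_activity(act_true, vois, cfg$injected_mbq * 1e6)
  dmap <- integrate_decay(dose_rate(act, cfg$dose_engine))
  doses <- vapply(voi_names, function(nm)
    if (any(vois[[nm]])) mean_dose(dmap, vois[[nm]]) else NA_real_, 0)
  lesion_doses <- vapply(vois$tumors, function(tm)
    if (any(tm)) mean_dose(dmap, tm) else NA_real_, 0)
  list(doses = doses, lesion_doses = lesion_doses)
}

#' Run the full pipeline for one synthetic patient
#'
#' Executes the complete study chain on one phantom: 4D phantom generation,
#' list-mode acquisition, respiratory gating (data-driven by default), gated
#' reconstruction and automated reference-phase selection, inter-phase
#' registration, the conventional 3D and motion-compensated 3Dcomp
#' reconstructions from the same list-mode data, VOI construction, voxel
#' dosimetry, and the comparison metrics, including ground-truth doses from
#' the phantom itself.
#'
#' @param spec a [phantom_spec()].
#' @param cfg a [run_config()].
#' @param patient_id identifier stored in the record.
#' @return a `comparison_record` list: `scalars` (one-row data.frame),
#'   `doses` (per-VOI table for 3D / 3Dcomp / truth), `lesions` (per-lesion
#'   features and PDD), plus provenance.
#' @export
run_patient <- function(spec, cfg = run_config(), patient_id = 1L) {
  ph <- generate_phase_set(spec, cfg$n_phases)
  acq <- cfg_acquisition(cfg, spec$seed)
  lm <- acquire_listmode(ph, acq, seed = spec$seed)

  if (cfg$gating == "truth") {
    labels <- lm$events$phase_true
    gating_method <- "truth"
  } else {
    feat <- rebin_listmode_features(lm, dt = cfg$signal_dt)
    sig <- laplacian_eigenmap_signal(feat)
    asg <- assign_phases(sig, cfg$n_phases, lm = lm)
    labels <- asg$event_labels
    gating_method <- asg$method
  }

  mu_ct <- ph$phases[[cfg$ct_phase + 1L]]$mu
  gated_recons <- reconstruct_gated_4d(lm, labels, cfg$n_phases, mu_ct, acq,
                                       cfg$gated_recon)
  ref <- as.integer(select_reference_phase(gated_recons, mu_ct,
                                           mu_liver = spec$attenuation$liver))
  gated <- bin_listmode(lm, labels, cfg$n_phases)
  transforms <- register_phases_2d_affine(gated, ref)

  recon_3d <- reconstruct_3d(lm, mu_ct, acq, cfg$recon)
  recon_comp <- reconstruct_3dcomp(lm, labels, transforms, ref, mu_ct, acq,
                                   cfg$recon)

  masks <- label_masks(ph$phases[[cfg$ct_phase + 1L]]$labels)
  arm3d <- analyze_arm(recon_3d, masks, cfg, "3D")
  armcp <- analyze_arm(recon_comp, masks, cfg, "3Dcomp")
  truth <- truth_arm(ph, masks, cfg)

  # amplitude from the gated extremes (liver axial centroid picks the pair)
  liver_reg <- dilate_mask(masks$liver, 2L)
  zc <- vapply(gated_recons, function(r) {
    w <- r$data * liver_reg
    if (sum(w) == 0) return(NA_real_)
    sum(slice.index(w, 3) * w) / sum(w)
  }, 0)
  exhale <- which.max(zc); inhale <- which.min(zc)
  amp_est <- if (exhale != inhale)
    estimate_amplitude(gated_recons[[exhale]], gated_recons[[inhale]],
                       masks$liver) else 0
  tr <- ph$true_translation_mm
  amp_true <- sqrt(sum((apply(tr, 2, max) - apply(tr, 2, min))^2))
  cc_amp_true <- max(tr[, 3]) - min(tr[, 3])

  pdd_voi <- pdd(armcp$doses, arm3d$doses)
  lesions <- do.call(rbind, lapply(seq_along(masks$tumors), function(t) {
    tf <- tumor_features(masks$tumors[[t]], masks$liver, spec$spacing,
                         cc_amplitude_mm = cc_amp_true)
    data.frame(patient = patient_id, lesion = t, t(tf$features),
               pdd = pdd(armcp$lesion_doses[t], arm3d$lesion_doses[t]),
               dose_3d = arm3d$lesion_doses[t],
               dose_3dcomp = armcp$lesion_doses[t],
               dose_true = truth$lesion_doses[t])
  }))

  scalars <- data.frame(
    patient = patient_id,
    amplitude_true_mm = amp_true, amplitude_est_mm = as.numeric(amp_est),
    lsf_3d = arm3d$lsf, lsf_3dcomp = armcp$lsf,
    tn_3d = arm3d$tn, tn_3dcomp = armcp$tn,
    activity_3d_gbq = arm3d$activity_gbq,
    activity_3dcomp_gbq = armcp$activity_gbq,
    pda = pda(armcp$activity_gbq, arm3d$activity_gbq),
    dose_lungs_3d = arm3d$doses[["lungs"]],
    dose_lungs_3dcomp = armcp$doses[["lungs"]],
    reference_phase = ref, gating = gating_method,
    dropped_events = attr(recon_comp, "n_dropped"))

  doses <- data.frame(voi = voi_names,
                      dose_3d = unname(arm3d$doses),
                      dose_3dcomp = unname(armcp$doses),
                      dose_true = unname(truth$doses),
                      pdd = unname(pdd_voi),
                      counts_3d = unname(arm3d$counts),
                      counts_3dcomp = unname(armcp$counts),
                      volume_ml = unname(arm3d$vols))

  structure(list(patient = patient_id, scalars = scalars, doses = doses,
                 lesions = lesions, spec = spec, config_preset = cfg$preset),
            class = "comparison_record")
}

#' Run a synthetic cohort end to end
#'
#' Samples (or accepts) a cohort of phantom specifications, runs
#' [run_patient()] on each, aggregates the comparison tables and applies the
#' statistical protocol (paired testing of 3D vs 3Dcomp series, Bland-Altman
#' agreement, Spearman predictor screen) when the cohort is large enough
#' (n >= 3; smaller cohorts return tables only).
#'
#' @param cfg a [run_config()].
#' @param specs optional list of [phantom_spec()]; default samples
#'   `cfg$cohort_size` patients with [sample_cohort()].
#' @return list: `records`, `scalars`, `doses`, `lesions` (aggregated
#'   data.frames), `stats` (or `NULL` for n < 3), `cfg`.
#' @export
run_cohort <- function(cfg = run_config(), specs = NULL) {
  if (is.null(specs))
    specs <- sample_cohort(cfg$cohort_size, seed = cfg$seed,
                           base_spec = base_phantom_spec(cfg),
                           vol_range_ml = if (cfg$preset == "desk") c(2, 15)
                                          else c(2, 200))
  records <- lapply(seq_along(specs), function(i)
    run_patient(specs[[i]], cfg, patient_id = i))
  scalars <- do.call(rbind, lapply(records, `[[`, "scalars"))
  doses <- do.call(rbind, lapply(seq_along(records), function(i)
    cbind(patient = i, records[[i]]$doses)))
  lesions <- do.call(rbind, lapply(records, `[[`, "lesions"))
  stats_out <- NULL
  if (nrow(scalars) >= 3) {
    stats_out <- list(
      lung_dose = stats_suite(scalars$dose_lungs_3dcomp, scalars$dose_lungs_3d),
      activity = stats_suite(scalars$activity_3dcomp_gbq, scalars$activity_3d_gbq),
      lung_dose_ba = bland_altman(scalars$dose_lungs_3dcomp, scalars$dose_lungs_3d),
      lsf_ba = bland_altman(scalars$lsf_3dcomp, scalars$lsf_3d))
    ok_tn <- stats::complete.cases(scalars$tn_3d, scalars$tn_3dcomp)
    if (sum(ok_tn) >= 3)
      stats_out$tn <- stats_suite(scalars$tn_3dcomp[ok_tn], scalars$tn_3d[ok_tn])
    if (!is.null(lesions) && nrow(lesions) >= 3) {
      preds <- lesions[, c("volume_ml", "min_border_dist_mm",
                           "mean_border_dist_mm", "cc_gap_top_mm",
                           "cc_amplitude_mm", "com_border_dist_mm",
                           "com_border_cc_dist_mm")]
      stats_out$tumor_predictors <-
        stats_suite(lesions$dose_3dcomp, lesions$dose_3d,
                    predictors = preds, target = lesions$pdd)$spearman
    }
  }
  list(records = records, scalars = scalars, doses = doses,
       lesions = lesions, stats = stats_out, cfg = cfg)
}

#' Write the cohort report bundle
#'
#' Persists the aggregated tables as CSV, a machine-readable JSON summary,
#' and the study figures (per-VOI PDD boxplots annotated with the number of
#' contours, Bland-Altman plots for lung dose / LSF / TN ratio, and tumor
#' PDD against volume and motion amplitude).
#'
#' @param bundle a [run_cohort()] result.
#' @param dir output directory.
#' @param figures write PNG figures (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$scalars, file.path(dir, "scalars.csv"), row.names = FALSE)
  utils::write.csv(bundle$doses, file.path(dir, "doses.csv"), row.names = FALSE)
  if (!is.null(bundle$lesions))
    utils::write.csv(bundle$lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  summ <- list(n_patients = nrow(bundle$scalars),
               median_pdd_by_voi = stats::aggregate(
                 pdd ~ voi, bundle$doses, stats::median),
               mean_abs_pda = mean(abs(bundle$scalars$pda)),
               mean_amplitude_mm = mean(bundle$scalars$amplitude_est_mm,
                                        na.rm = TRUE))
  if (!is.null(bundle$stats))
    summ$tests <- list(
      lung_dose_branch = bundle$stats$lung_dose$branch,
      lung_dose_p = bundle$stats$lung_dose$p_value,
      activity_p = bundle$stats$activity$p_value)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (figures) report_figures(bundle, dir)
  invisible(dir)
}

report_figures <- function(bundle, dir) {
  fig <- function(name, expr) {
    grDevices::png(file.path(dir, name), width = 900, height = 600)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  d <- bundle$doses[is.finite(bundle$doses$pdd), ]
  fig("pdd_by_voi.png", {
    bp <- graphics::boxplot(pdd ~ voi, d, ylab = "PDD (%)",
                            main = "Dose difference 3Dcomp vs 3D by VOI")
    n <- table(d$voi)[bp$names]
    graphics::text(seq_along(bp$names), max(d$pdd), labels = n, pos = 3,
                   xpd = NA)
  })
  ba_fig <- function(name, ba, lab) fig(name, {
    graphics::plot(ba$pairs$mean, ba$pairs$diff, xlab = paste("mean", lab),
                   ylab = paste("difference", lab), main = "Bland-Altman")
    graphics::abline(h = c(ba$mean_diff, ba$loa), lty = c(1, 2, 2))
  })
  if (!is.null(bundle$stats)) {
    ba_fig("ba_lung_dose.png", bundle$stats$lung_dose_ba, "lung dose (Gy)")
    ba_fig("ba_lsf.png", bundle$stats$lsf_ba, "LSF (%)")
  }
  if (!is.null(bundle$lesions) && nrow(bundle$lesions) > 0) {
    fig("pdd_vs_volume.png",
        graphics::plot(bundle$lesions$volume_ml, bundle$lesions$pdd,
                       log = "x", xlab = "tumor volume (mL)", ylab = "PDD (%)"))
    fig("pdd_vs_amplitude.png",
        graphics::plot(bundle$lesions$cc_amplitude_mm, bundle$lesions$pdd,
                       xlab = "CC amplitude (mm)", ylab = "PDD (%)"))
  }
  invisible(dir)
}

#' Command-line entry point
#'
#' Minimal CLI used by `inst/cli/mocodose`: subcommands `simulate` (write a
#' 4D phantom), `run-all` (cohort pipeline + report). Options come from a
#' JSON config file.
#'
#' @param args character vector, e.g. `c("run-all", "--config", "cfg.json",
#'   "--out", "out/")`.
#' @return invisibly, the output directory.
#' @export
mocodose_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: mocodose <simulate|run-all> [--config f.json] [--out dir]")
  cmd <- args[1]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out <- get_opt("--out", "mocodose_out")
  cfgf <- get_opt("--config")
  opts <- if (!is.null(cfgf)) jsonlite::read_json(cfgf, simplifyVector = TRUE) else list()
  cfg <- do.call(run_config, opts)
  if (cmd == "simulate") {
    ph <- generate_phase_set(base_phantom_spec(cfg), cfg$n_phases)
    write_phantom4d(ph, out)
  } else if (cmd == "run-all") {
    bundle <- run_cohort(cfg)
    write_report(bundle, out)
  } else {
    stop(sprintf("unknown command '%s'", cmd))
  }
  invisible(out)
}
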