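#' Specify a digital thorax/abdomen phantom
#'
#' Builds the parameter set for a 4D digital phantom emulating the anatomy and
#' 99mTc-MAA biodistribution of a radioembolization planning scan: a soft
#' tissue body, two lungs, a liver with 1-3 spherical tumors, and cyclic
#' breathing translation of the liver+tumor complex. Organ geometry defaults
#' are fractions of the grid extent so that the same anatomy scales from the
#' desk grid (32^3) to the acquisition grid (128^3).
#'
#' Axis/motion conventions: x = LR, y = AP, z = CC. Phase 0 is end-exhale with
#' the liver at its most cranial position; over the cycle the complex moves by
#' `-amplitude_mm * (1 - cos(2*pi*p/n))/2` (caudal/posterior), so the static
#' lungs are never entered. `amplitude_mm` holds nonnegative peak-to-peak
#' magnitudes per axis (LR, AP, CC); defaults follow the cohort means of a
#' clinical planning population (~0.9 cm CC, ~0.4 cm AP).
#'
#' @param grid_shape integer length-3, voxels per axis (default 64^3).
#' @param spacing voxel spacing mm (default 4.418 isotropic, the acquisition
#'   bin size).
#' @param organs named list of ellipsoids (fractions of the extent):
#'   `body`, `liver`, `lung_left`, `lung_right`, each `list(center, semiaxes)`.
#' @param tumors list of `list(center_mm, radius_mm, uptake)`; `center_mm` may
#'   be `NULL` to use the default dome-adjacent position.
#' @param conc_background,conc_liver relative activity concentrations
#'   (arbitrary rate units per voxel before normalization).
#' @param attenuation named list of linear attenuation coefficients at
#'   140.5 keV in 1/mm for `air`, `lung`, `soft`, `liver`.
#' @param amplitude_mm nonnegative length-3 peak-to-peak motion magnitudes mm
#'   (LR, AP, CC).
#' @param period_s breathing period in seconds.
#' @param lung_shunt_fraction_true fraction of liver+lung activity shunted to
#'   the lungs, in [0, 0.5].
#' @param moving_organs organs translated by breathing: `c("liver", "lungs")`
#'   (default, diaphragm-coupled lungs) or `"liver"` only. Static lungs make
#'   the lung-dose comparison structurally one-sided (see the methods
#'   vignette), so the coupled default is recommended.
#' @param total_rate total emission rate of the phantom (expected detected-
#'   geometry counts/s before attenuation losses); activity maps are
#'   normalized to sum to this.
#' @param seed integer seed recorded in the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(4.418, 4.418, 4.418),
                         organs = NULL,
                         tumors = list(list(center_mm = NULL, radius_mm = NULL,
                                            uptake = 5)),
                         conc_background = 0.02,
                         conc_liver = 1,
                         attenuation = list(air = 0, lung = 0.004,
                                            soft = 0.015, liver = 0.0158),
                         amplitude_mm = c(0, 4, 9),
                         period_s = 5,
                         lung_shunt_fraction_true = 0.05,
                         moving_organs = c("liver", "lungs"),
                         total_rate = 2000,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- grid_shape * spacing
  if (is.null(organs)) {
    organs <- list(
      body       = list(center = c(0.50, 0.50, 0.50), semiaxes = c(0.46, 0.38, 0.48)),
      liver      = list(center = c(0.38, 0.50, 0.43), semiaxes = c(0.25, 0.20, 0.23)),
      lung_left  = list(center = c(0.28, 0.50, 0.82), semiaxes = c(0.19, 0.24, 0.16)),
      lung_right = list(center = c(0.72, 0.50, 0.82), semiaxes = c(0.19, 0.24, 0.16)))
  }
  # resolve default tumor geometry (fractions of extent)
  tumors <- lapply(tumors, function(tm) {
    if (is.null(tm$center_mm)) tm$center_mm <- c(0.38, 0.50, 0.54) * extent
    if (is.null(tm$radius_mm)) tm$radius_mm <- 0.055 * min(extent)
    if (is.null(tm$uptake)) tm$uptake <- 5
    tm
  })
  spec <- structure(list(
    grid_shape = grid_shape, spacing = spacing, extent = extent,
    organs = organs, tumors = tumors,
    conc_background = conc_background, conc_liver = conc_liver,
    attenuation = attenuation,
    amplitude_mm = as.numeric(amplitude_mm), period_s = period_s,
    lung_shunt_fraction_true = lung_shunt_fraction_true,
    moving_organs = moving_organs,
    total_rate = total_rate, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(spacing <= 0)) stop("phantom_spec: spacing must be > 0")
    if (any(amplitude_mm < 0)) stop("phantom_spec: amplitudes must be >= 0")
    if (period_s <= 0) stop("phantom_spec: period must be > 0")
    if (lung_shunt_fraction_true < 0 || lung_shunt_fraction_true > 0.5)
      stop("phantom_spec: lung_shunt_fraction_true must be in [0, 0.5]")
    for (tm in tumors)
      if (tm$radius_mm <= 0) stop("phantom_spec: tumor radii must be > 0")
  })
  invisible(spec)
}

# logical mask of an axis-aligned ellipsoid (mm geometry, voxel centers)
ellipsoid_mask <- function(grid_shape, spacing, center_mm, semiaxes_mm) {
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - 0.5) * spacing[a] - center_mm[a]) / semiaxes_mm[a])
  x2 <- ax[[1]]^2
  y2 <- ax[[2]]^2
  z2 <- ax[[3]]^2
  outer(outer(x2, y2, "+"), z2, "+") <= 1
}

#' Build the static (end-exhale) phantom
#'
#' Rasterizes the organ geometry into an activity map, an attenuation map at
#' 140.5 keV and an organ label map. Label codes: 0 air, 1 body (soft tissue),
#' 2 lung, 3 liver, 10+t tumor t. Lung activity is set so that the lung share
#' of total liver+lung activity equals `lung_shunt_fraction_true` exactly, and
#' the whole activity map is normalized to sum to `total_rate`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `activity`, `mu`, `labels` ([vol3d()]) and `spec`.
#'   A tumor placed (even partially) outside the liver is a geometry error.
#' @export
build_static_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; sp <- spec$spacing; ex <- spec$extent
  org <- function(o) ellipsoid_mask(gs, sp, o$center * ex, o$semiaxes * ex)
  body <- org(spec$organs$body)
  liver <- org(spec$organs$liver) & body
  lungs <- (org(spec$organs$lung_left) | org(spec$organs$lung_right)) & body
  lungs <- lungs & !liver                       # liver wins shared voxels
  if (!any(liver)) stop("build_static_phantom: empty liver")

  tumor_masks <- list()
  for (t in seq_along(spec$tumors)) {
    tm <- spec$tumors[[t]]
    m <- ellipsoid_mask(gs, sp, tm$center_mm, rep(tm$radius_mm, 3))
    if (!any(m)) stop(sprintf("tumor %d rasterizes to zero voxels", t))
    if (any(m & !liver))
      stop(sprintf("tumor %d lies (partly) outside the liver", t))
    tumor_masks[[t]] <- m
  }
  tumor_any <- Reduce(`|`, tumor_masks, array(FALSE, gs))

  labels <- array(0, gs)
  labels[body] <- 1
  labels[lungs] <- 2
  labels[liver] <- 3
  for (t in seq_along(tumor_masks)) labels[tumor_masks[[t]]] <- 10 + t

  activity <- array(0, gs)
  activity[body] <- spec$conc_background
  activity[liver] <- spec$conc_liver
  for (t in seq_along(tumor_masks))
    activity[tumor_masks[[t]]] <- spec$conc_liver * spec$tumors[[t]]$uptake
  a_complex <- sum(activity[liver])             # liver incl. tumors
  s <- spec$lung_shunt_fraction_true
  if (any(lungs) && s > 0) {
    activity[lungs] <- s / (1 - s) * a_complex / sum(lungs)
  } else {
    activity[lungs] <- 0
  }
  tot <- sum(activity)
  if (tot > 0) activity <- activity * (spec$total_rate / tot)

  mu <- array(spec$attenuation$air, gs)
  mu[body] <- spec$attenuation$soft
  mu[lungs] <- spec$attenuation$lung
  mu[liver] <- spec$attenuation$liver           # tumors share liver class

  list(activity = vol3d(activity, sp), mu = vol3d(mu, sp),
       labels = vol3d(labels, sp), spec = spec)
}

#' Organ masks from a phantom label map
#'
#' Splits a label map (0 air, 1 body, 2 lung, 3 liver, 10+t tumor t) into
#' logical organ masks; the liver mask includes tumor voxels.
#'
#' @param labels a [vol3d()] label map or plain array.
#' @return list of logical arrays: `body`, `lungs`, `liver`, `tumors`
#'   (per-lesion list), `tumor_any`.
#' @export
label_masks <- function(labels) {
  lab <- if (inherits(labels, "vol3d")) labels$data else labels
  tumor_codes <- sort(unique(lab[lab >= 10]))
  tumors <- lapply(tumor_codes, function(code) lab == code)
  list(body = lab >= 1, lungs = lab == 2,
       liver = lab == 3 | lab >= 10,            # liver incl. tumors
       tumors = tumors,
       tumor_any = lab >= 10)
}

# round to nearest integer, ties toward lower index
round_half_down <- function(x) ceiling(x - 0.5)

# cosine phase displacement factor, phase p of n (0-based): end-exhale dwell
phase_fraction <- function(p, n) (1 - cos(2 * pi * p / n)) / 2

#' Generate the 4D breathing phantom
#'
#' Produces one activity/attenuation/label map per respiratory phase by rigid
#' integer-voxel translation of the moving-organ complex (liver + tumors,
#' plus lungs when diaphragm-coupled; nearest-neighbor shift, ties toward
#' the lower index), leaving the body static. Phase p
#' of n displaces the complex by `-amplitude_mm * (1 - cos(2*pi*p/n))/2`,
#' so phase 0 is end-exhale and phase n/2 end-inhale. Total activity is
#' conserved exactly across phases.
#'
#' @param spec a [phantom_spec()].
#' @param n_phases number of respiratory phases (default 8, the gating
#'   default).
#' @return object of class `phantom4d`: `phases` (list of
#'   activity/mu/labels), `true_translation_mm` (applied, voxel-quantized),
#'   `nominal_translation_mm`, `n_phases`, `spec`.
#' @export
generate_phase_set <- function(spec, n_phases = 8L) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L) stop("generate_phase_set: n_phases must be >= 1")
  base <- build_static_phantom(spec)
  gs <- spec$grid_shape; sp <- spec$spacing
  lab0 <- base$labels$data
  complex_mask <- lab0 == 3 | lab0 >= 10
  if ("lungs" %in% spec$moving_organs) complex_mask <- complex_mask | lab0 == 2

  # base maps with the complex carved out (vacated voxels become body)
  act0 <- base$activity$data
  mu0 <- base$mu$data
  bg_act <- act0[which(lab0 == 1)[1]]           # body background concentration
  act_wo <- act0; act_wo[complex_mask] <- bg_act
  mu_wo <- mu0; mu_wo[complex_mask] <- spec$attenuation$soft
  lab_wo <- lab0; lab_wo[complex_mask] <- 1

  idx <- which(complex_mask)
  arr_idx <- which(complex_mask, arr.ind = TRUE)
  nominal <- matrix(0, n_phases, 3)
  applied <- matrix(0, n_phases, 3)
  phases <- vector("list", n_phases)
  for (p in seq_len(n_phases)) {
    d_mm <- -spec$amplitude_mm * phase_fraction(p - 1L, n_phases)
    nominal[p, ] <- d_mm
    d_vox <- round_half_down(d_mm / sp)
    applied[p, ] <- d_vox * sp
    tgt <- sweep(arr_idx, 2, d_vox, "+")
    if (any(tgt < 1L) || any(sweep(tgt, 2, gs, ">")))
      stop("generate_phase_set: liver complex shifted outside the grid")
    lin <- tgt[, 1] + (tgt[, 2] - 1L) * gs[1] + (tgt[, 3] - 1L) * gs[1] * gs[2]
    if (any(lab_wo[lin] != 1))
      stop("generate_phase_set: moving complex shifted into lung or air")
    act_p <- act_wo; act_p[lin] <- act0[idx]
    mu_p <- mu_wo; mu_p[lin] <- mu0[idx]
    lab_p <- lab_wo; lab_p[lin] <- lab0[idx]
    phases[[p]] <- list(activity = vol3d(act_p, sp), mu = vol3d(mu_p, sp),
                        labels = vol3d(lab_p, sp))
  }
  structure(list(phases = phases, n_phases = n_phases,
                 true_translation_mm = applied,
                 nominal_translation_mm = nominal, spec = spec),
            class = "phantom4d")
}

# truncated normal draw via inverse-cdf (deterministic under set.seed)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Sample a synthetic patient cohort
#'
#' Draws per-patient phantom specifications: breathing amplitude norms from a
#' truncated normal emulating the clinical distribution (mean 9.5 mm, sd
#' 2.7 mm, truncated to the observed range 3.4-16.8 mm), tumor volumes
#' log-uniform over `vol_range_ml`, tumor positions jittered inside the liver,
#' and tumor uptake multipliers uniform over `uptake_range`.
#'
#' @param n_patients cohort size.
#' @param seed integer seed (the whole cohort is deterministic given the
#'   seed).
#' @param base_spec template [phantom_spec()]; geometry and grid are shared.
#' @param amp_mean,amp_sd,amp_range truncated-normal parameters (mm) for the
#'   amplitude norm.
#' @param vol_range_ml log-uniform tumor volume range in mL. Radii are capped
#'   at 85% of the smallest liver semiaxis so lesions always fit.
#' @param uptake_range tumor-to-liver uptake multiplier range.
#' @param direction motion direction unit vector applied to the sampled norm
#'   (magnitudes per axis; default CC-dominant).
#' @return list of `phantom_spec` objects.
#' @export
sample_cohort <- function(n_patients, seed = 1L, base_spec = phantom_spec(),
                          amp_mean = 9.5, amp_sd = 2.7,
                          amp_range = c(3.4, 16.8),
                          vol_range_ml = c(2, 200),
                          uptake_range = c(3, 8),
                          direction = c(0, 0.4, 0.9)) {
  if (n_patients < 1) stop("sample_cohort: n_patients must be >= 1")
  set.seed(as.integer(seed))
  direction <- abs(direction) / sqrt(sum(direction^2))
  liv <- base_spec$organs$liver
  semi_mm <- liv$semiaxes * base_spec$extent
  center_mm <- liv$center * base_spec$extent
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    amp <- rtruncnorm1(1, amp_mean, amp_sd, amp_range[1], amp_range[2])
    vol_ml <- exp(stats::runif(1, log(vol_range_ml[1]), log(vol_range_ml[2])))
    r <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
    r <- min(r, 0.85 * min(semi_mm))
    # rejection-sample a center whose r-sphere provably fits in the liver
    repeat {
      off <- stats::runif(3, -1, 1) * pmax(semi_mm - r, 0)
      if (sum((off / pmax(semi_mm - r, 1e-9))^2) <= 0.9^2) break
    }
    uptake <- stats::runif(1, uptake_range[1], uptake_range[2])
    sp <- base_spec
    sp$amplitude_mm <- direction * amp
    sp$tumors <- list(list(center_mm = center_mm + off, radius_mm = r,
                           uptake = uptake))
    sp$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    out[[i]] <- sp
  }
  out
}

#' Write phantom phases to disk
#'
#' Phases are written as MetaImage volumes plus a JSON sidecar holding the
#' spec and the true per-phase translations.
#'
#' @param ph4d a [generate_phase_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom4d <- function(ph4d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_len(ph4d$n_phases)) {
    write_mha(ph4d$phases[[p]]$activity, file.path(dir, sprintf("activity_ph%02d.mha", p - 1)))
    write_mha(ph4d$phases[[p]]$mu, file.path(dir, sprintf("mu_ph%02d.mha", p - 1)))
    write_mha(ph4d$phases[[p]]$labels, file.path(dir, sprintf("labels_ph%02d.mha", p - 1)))
  }
  side <- list(
    spec = ph4d$spec[setdiff(names(ph4d$spec), "organs")],
    true_translation_mm = ph4d$true_translation_mm,
    nominal_translation_mm = ph4d$nominal_translation_mm)
  jsonlite::write_json(side, file.path(dir, "phantom4d.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
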