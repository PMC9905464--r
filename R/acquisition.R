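#' Specify the SPECT acquisition
#'
#' Camera and protocol parameters for the step-and-shoot acquisition:
#' 60 projections over 360 degrees, 25 s per projection, a primary energy
#' window centered at 140.5 keV with total width 20% of center
#' (126.45-154.55 keV) and a scatter window at 120 keV with total width 10%
#' of center (114-126 keV), and a depth-dependent Gaussian PSF whose FWHM is
#' 7.4 mm at 100 mm from the collimator (LEHR-like) and grows linearly with
#' distance. Scatter is a kernel surrogate: a broad Gaussian blur of the
#' unattenuated projection feeds both windows.
#'
#' @param n_projections number of projection angles (default 60).
#' @param arc_deg covered arc in degrees (default 360).
#' @param time_per_projection_s dwell per projection in seconds (default 25).
#' @param primary_kev,primary_width_frac primary window center and fractional
#'   total width (defaults 140.5 keV, 0.20).
#' @param scatter_kev,scatter_width_frac scatter window center and fractional
#'   total width (defaults 120 keV, 0.10).
#' @param psf_fwhm_ref_mm,psf_dist_ref_mm,psf_slope PSF model
#'   `FWHM(d) = intercept + slope * d` with the intercept fixed by
#'   `FWHM(dist_ref) = fwhm_ref` (defaults 7.4 mm at 100 mm, slope
#'   0.044 mm/mm).
#' @param det_dist_mm distance from the rotation axis to the detector plane
#'   (mm).
#' @param scatter_fraction scatter-window counts as a fraction of geometric
#'   primary counts (default 0.3).
#' @param scatter_primary_fraction fraction of the broad-blurred projection
#'   contaminating the primary window (default 0.3).
#' @param scatter_fwhm_mm FWHM of the broad scatter kernel (default 40 mm).
#' @param seed integer seed for the Poisson acquisition.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_projections = 60L, arc_deg = 360,
                             time_per_projection_s = 25,
                             primary_kev = 140.5, primary_width_frac = 0.20,
                             scatter_kev = 120, scatter_width_frac = 0.10,
                             psf_fwhm_ref_mm = 7.4, psf_dist_ref_mm = 100,
                             psf_slope = 0.044,
                             det_dist_mm = 250,
                             scatter_fraction = 0.3,
                             scatter_primary_fraction = 0.3,
                             scatter_fwhm_mm = 40,
                             seed = 1L) {
  if (n_projections < 1) stop("acquisition_spec: n_projections must be >= 1")
  if (primary_width_frac <= 0 || scatter_width_frac <= 0)
    stop("acquisition_spec: window widths must be > 0")
  if (psf_fwhm_ref_mm <= 0) stop("acquisition_spec: PSF FWHM must be > 0")
  structure(list(
    n_projections = as.integer(n_projections), arc_deg = arc_deg,
    time_per_projection_s = time_per_projection_s,
    primary_kev = primary_kev, primary_width_frac = primary_width_frac,
    scatter_kev = scatter_kev, scatter_width_frac = scatter_width_frac,
    psf_fwhm_ref_mm = psf_fwhm_ref_mm, psf_dist_ref_mm = psf_dist_ref_mm,
    psf_slope = psf_slope,
    psf_intercept = psf_fwhm_ref_mm - psf_slope * psf_dist_ref_mm,
    det_dist_mm = det_dist_mm,
    scatter_fraction = scatter_fraction,
    scatter_primary_fraction = scatter_primary_fraction,
    scatter_fwhm_mm = scatter_fwhm_mm,
    seed = as.integer(seed)), class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @param acq an `acquisition_spec`.
#' @export
projection_angles <- function(acq) {
  (seq_len(acq$n_projections) - 1) * acq$arc_deg / acq$n_projections
}

# keV widths of the two energy windows
window_widths_kev <- function(acq) {
  c(primary = acq$primary_kev * acq$primary_width_frac,
    scatter = acq$scatter_kev * acq$scatter_width_frac)
}

#' Forward-project an activity map
#'
#' Attenuated parallel-beam projection: line integrals of activity weighted by
#' `exp(-integral of mu)` from the emission voxel to the detector (on the +y
#' side after rotating the volume by the projection angle about z), convolved
#' slice-by-slice with a Gaussian whose FWHM grows linearly with
#' source-detector distance. The detector grid is one bin per voxel column
#' (u = x, v = z, bin size = in-plane spacing).
#'
#' @param activity,mu [vol3d()] maps sharing geometry (isotropic x/y spacing).
#' @param acq an [acquisition_spec()].
#' @param angle_deg camera angle in degrees.
#' @param use_att,use_psf toggles for attenuation and PSF modeling.
#' @return numeric matrix `[n_u, n_v]` of expected counts-rate.
#' @export
forward_project <- function(activity, mu, acq, angle_deg,
                            use_att = TRUE, use_psf = TRUE) {
  stopifnot_same_geometry(activity, mu, "activity/attenuation maps")
  sp <- activity$spacing
  if (abs(sp[1] - sp[2]) > 1e-9)
    stop("forward_project: x/y spacing must be isotropic for rotation")
  forward_project_cpp(activity$data, mu$data, angle_deg * pi / 180,
                      sp[1], sp[2], sp[3], acq$det_dist_mm,
                      acq$psf_intercept, acq$psf_slope, use_att, use_psf)
}

#' @rdname forward_project
#' @param proj projection matrix to backproject.
#' @export
back_project <- function(proj, mu, acq, angle_deg,
                         use_att = TRUE, use_psf = TRUE) {
  sp <- mu$spacing
  d <- dim(mu$data)
  vol3d(back_project_cpp(proj, mu$data, angle_deg * pi / 180,
                         sp[1], sp[2], sp[3], acq$det_dist_mm,
                         acq$psf_intercept, acq$psf_slope, use_att, use_psf,
                         d[1], d[2], d[3]),
        spacing = sp, origin = mu$origin)
}

#' Expected scatter-window projection
#'
#' Kernel surrogate for physical scatter: the unattenuated, PSF-free
#' projection convolved with a broad Gaussian (`scatter_fwhm_mm`) and scaled
#' by `scatter_fraction`. The same broad projection scaled by
#' `scatter_primary_fraction` contaminates the primary window during
#' acquisition, which is what the dual-energy-window correction removes.
#'
#' @inheritParams forward_project
#' @return numeric matrix of expected scatter-window counts-rate.
#' @export
simulate_scatter_window <- function(activity, mu, acq, angle_deg) {
  broad <- scatter_broad_projection(activity, mu, acq, angle_deg)
  acq$scatter_fraction * broad
}

scatter_broad_projection <- function(activity, mu, acq, angle_deg) {
  geom <- forward_project(activity, mu, acq, angle_deg,
                          use_att = FALSE, use_psf = FALSE)
  sig_u <- acq$scatter_fwhm_mm / 2.354820045 / activity$spacing[1]
  sig_v <- acq$scatter_fwhm_mm / 2.354820045 / activity$spacing[3]
  blur2_cpp(geom, sig_u, sig_v)
}

# time intervals (within [t0, t1)) during which the breathing cycle is in
# phase p (0-based) of n equal-time phase bins. Intervals are CENTERED on
# p*T/n (phase p covers [(p-1/2), (p+1/2)) * T/n of each cycle), so the
# displacement assigned to phase p — the waveform value at p*T/n — is the
# value at its interval's center, keeping the piecewise-constant position
# waveform symmetric about end-exhale.
phase_intervals <- function(t0, t1, period, n_phases, p) {
  if (n_phases == 1L) return(matrix(c(t0, t1), 1))
  first_c <- floor(t0 / period) - 1L; last_c <- floor((t1 - 1e-12) / period) + 1L
  starts <- (first_c:last_c) * period + (p - 0.5) * period / n_phases
  ends <- starts + period / n_phases
  lo <- pmax(starts, t0); hi <- pmin(ends, t1)
  keep <- hi > lo
  cbind(lo[keep], hi[keep])
}

# true phase of a time point under the centered-interval convention
phase_of_time <- function(t, period, n_phases) {
  if (n_phases == 1L) return(rep(0L, length(t)))
  as.integer(round((t %% period) / period * n_phases) %% n_phases)
}

# expected (noiseless) per-phase, per-angle rate projections for both windows
expected_projection_rates <- function(phantom, acq) {
  angles <- projection_angles(acq)
  nph <- phantom$n_phases
  d <- dim(phantom$phases[[1]]$activity$data)
  prim <- array(0, c(d[1], d[3], length(angles), nph))
  scat <- array(0, c(d[1], d[3], length(angles), nph))
  for (p in seq_len(nph)) {
    act <- phantom$phases[[p]]$activity
    mu <- phantom$phases[[p]]$mu
    for (a in seq_along(angles)) {
      broad <- scatter_broad_projection(act, mu, acq, angles[a])
      prim[, , a, p] <- forward_project(act, mu, acq, angles[a]) +
        acq$scatter_primary_fraction * broad
      scat[, , a, p] <- acq$scatter_fraction * broad
    }
  }
  list(primary = prim, scatter = scat, angles = angles)
}

#' Acquire list-mode data over a breathing phantom
#'
#' Step-and-shoot acquisition: for each projection the dwell time is
#' partitioned among respiratory phases according to the breathing cycle,
#' expected projections are computed per phase (primary window = attenuated
#' PSF-blurred projection plus scatter contamination; scatter window = broad
#' kernel surrogate) and Poisson-sampled. Every detected count becomes an
#' event `(time, projection, detector bin, window, true phase)` with the
#' timestamp uniform within its phase's dwell intervals.
#'
#' @param phantom a [generate_phase_set()] result.
#' @param acq an [acquisition_spec()].
#' @param seed integer; overrides `acq$seed` when given.
#' @return object of class `listmode`: `events` data.frame (`t`, `proj`,
#'   `iu`, `iv`, `window` 1=primary/2=scatter, `phase_true` 0-based),
#'   `acq`, `angles_deg`, `n_phases`, `period_s`, `rates` (expected rate
#'   projections, kept for oracle checks).
#' @export
acquire_listmode <- function(phantom, acq, seed = NULL) {
  if (sum(phantom$phases[[1]]$activity$data) <= 0)
    stop("acquire_listmode: phantom has no activity")
  set.seed(if (is.null(seed)) acq$seed else as.integer(seed))
  rates <- expected_projection_rates(phantom, acq)
  angles <- rates$angles
  nph <- phantom$n_phases
  tp <- acq$time_per_projection_s
  period <- phantom$spec$period_s
  nu <- dim(rates$primary)[1]; nv <- dim(rates$primary)[2]

  cols <- list(t = list(), proj = list(), iu = list(), iv = list(),
               window = list(), phase = list())
  ev_i <- 0L
  for (a in seq_along(angles)) {
    t0 <- (a - 1) * tp; t1 <- a * tp
    for (p in seq_len(nph)) {
      iv_list <- phase_intervals(t0, t1, period, nph, p - 1L)
      dwell <- sum(iv_list[, 2] - iv_list[, 1])
      if (dwell <= 0) next
      for (w in 1:2) {
        lam <- (if (w == 1) rates$primary[, , a, p] else rates$scatter[, , a, p]) * dwell
        counts <- stats::rpois(length(lam), lam)
        nz <- which(counts > 0L)
        if (!length(nz)) next
        n_ev <- sum(counts[nz])
        iu <- rep(((nz - 1L) %% nu) + 1L, counts[nz])
        ivv <- rep(((nz - 1L) %/% nu) + 1L, counts[nz])
        # timestamps uniform over the union of this phase's dwell intervals
        u <- stats::runif(n_ev) * dwell
        cum <- cumsum(iv_list[, 2] - iv_list[, 1])
        seg <- findInterval(u, c(0, cum[-length(cum)] + 1e-15))
        tt <- iv_list[seg, 1] + (u - c(0, cum)[seg])
        ev_i <- ev_i + 1L
        cols$t[[ev_i]] <- tt; cols$proj[[ev_i]] <- rep(a, n_ev)
        cols$iu[[ev_i]] <- iu; cols$iv[[ev_i]] <- ivv
        cols$window[[ev_i]] <- rep(w, n_ev)
        cols$phase[[ev_i]] <- rep(p - 1L, n_ev)
      }
    }
  }
  ev <- data.frame(t = unlist(cols$t), proj = as.integer(unlist(cols$proj)),
                   iu = as.integer(unlist(cols$iu)),
                   iv = as.integer(unlist(cols$iv)),
                   window = as.integer(unlist(cols$window)),
                   phase_true = as.integer(unlist(cols$phase)))
  ev <- ev[order(ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, acq = acq, angles_deg = angles,
                 det_dim = c(nu, nv), n_phases = nph, period_s = period,
                 scan_time_s = length(angles) * tp, rates = rates),
            class = "listmode")
}

#' Bin list-mode events into gated projection sets
#'
#' Partitions events by a per-event phase assignment and histograms each
#' phase's events into per-angle projections for both energy windows. Summing
#' the gated projections over phases reproduces the ungated projections
#' count-exactly.
#'
#' @param lm a [acquire_listmode()] result.
#' @param labels integer vector of 0-based phase labels, one per event.
#' @param n_phases number of phases covered by `labels`.
#' @return list of `n_phases` gated sets, each
#'   `list(primary, scatter)` arrays `[n_u, n_v, n_projections]`, with the
#'   angle vector as attribute `angles_deg`.
#' @export
bin_listmode <- function(lm, labels, n_phases) {
  ev <- lm$events
  if (length(labels) != nrow(ev)) stop("bin_listmode: one label per event required")
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_phases))
    stop("bin_listmode: phase label out of range")
  nu <- lm$det_dim[1]; nv <- lm$det_dim[2]; na <- length(lm$angles_deg)
  nbin <- nu * nv * na
  out <- vector("list", n_phases)
  lin <- ev$iu + (ev$iv - 1L) * nu + (ev$proj - 1L) * nu * nv
  for (p in seq_len(n_phases)) {
    sel_p <- labels == (p - 1L)
    prim <- tabulate(lin[sel_p & ev$window == 1L], nbins = nbin)
    scat <- tabulate(lin[sel_p & ev$window == 2L], nbins = nbin)
    out[[p]] <- list(primary = array(prim, c(nu, nv, na)),
                     scatter = array(scat, c(nu, nv, na)))
  }
  attr(out, "angles_deg") <- lm$angles_deg
  out
}

#' @rdname bin_listmode
#' @export
ungated_projections <- function(lm) {
  bin_listmode(lm, rep(0L, nrow(lm$events)), 1L)[[1L]]
}
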