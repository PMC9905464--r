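#' 90Y decay model
#'
#' Mono-exponential decay with a 64 h half-life (the planning convention);
#' the time-integration factor is `T_half / ln 2` in seconds, so an initial
#' dose rate `r0` integrates to `r0 * T_half * 3600 / ln 2` Gy.
#'
#' @param half_life_h half-life in hours (default 64).
#' @return list with `half_life_h` and `factor_s`.
#' @export
decay_model <- function(half_life_h = 64) {
  if (half_life_h <= 0) stop("decay_model: half-life must be > 0")
  list(half_life_h = half_life_h, factor_s = half_life_h * 3600 / log(2))
}

MEV_TO_J <- 1.602176634e-13

#' Synthetic 90Y radial dose-point-kernel table
#'
#' A deterministic stand-in for a Monte Carlo dose-point kernel: the radial
#' energy-density profile is exponential, `f(r) = c * exp(-r / r0)`,
#' truncated at `r_max` (the approximate maximum beta range in soft tissue)
#' and normalized so the deposited energy integrates to one decay's mean beta
#' energy. This is a SYNTHETIC kernel — an analytic surrogate, not a
#' published table; the same table ships as
#' `inst/extdata/y90_dpk_synthetic.csv`.
#'
#' @param r_step radial step mm.
#' @param r0 exponential fall-off mm (default 2.2).
#' @param r_max truncation radius mm (default 11, ~90Y max range).
#' @return data.frame with `radius_mm` (bin centers) and
#'   `energy_fraction_per_mm3` such that
#'   `sum(4*pi*r^2*dr * f) = 1`.
#' @export
y90_kernel_table <- function(r_step = 0.1, r0 = 2.2, r_max = 11) {
  r <- seq(r_step / 2, r_max, by = r_step)
  f <- exp(-r / r0)
  shell <- 4 * pi * r^2 * r_step
  f <- f / sum(f * shell)
  data.frame(radius_mm = r, energy_fraction_per_mm3 = f)
}

# discrete voxel kernel from the radial table, normalized to unit energy
build_dose_kernel <- function(spacing, table = y90_kernel_table()) {
  r_max <- max(table$radius_mm)
  half <- pmax(1L, ceiling(r_max / spacing))
  ax <- lapply(1:3, function(a) (-half[a]:half[a]) * spacing[a])
  k <- array(0, 2L * half + 1L)
  for (i in seq_along(ax[[1]])) for (j in seq_along(ax[[2]]))
    for (l in seq_along(ax[[3]])) {
      r <- sqrt(ax[[1]][i]^2 + ax[[2]][j]^2 + ax[[3]][l]^2)
      if (r <= r_max) {
        fi <- stats::approx(table$radius_mm, table$energy_fraction_per_mm3,
                            xout = max(r, min(table$radius_mm)), rule = 2)$y
        k[i, j, l] <- fi
      }
    }
  k / sum(k)                                    # unit energy per decay
}

#' Calibrate a reconstruction to absolute activity
#'
#' Scales the reconstructed counts so that the counts within the liver and
#' lungs VOIs sum to the injected activity: `f = injected / sum(counts in
#' liver + lungs)`; every voxel (including extrahepatic counts, which are
#' excluded from the normalization sum) is multiplied by `f`.
#'
#' @param recon a [vol3d()] reconstruction.
#' @param vois a [derive_vois()] result (uses `liver` and `lungs`).
#' @param injected_bq injected activity in Bq.
#' @return a [vol3d()] activity map (Bq per voxel) with attribute
#'   `injected_bq`.
#' @export
calibrate_activity <- function(recon, vois, injected_bq) {
  if (injected_bq <= 0) stop("calibrate_activity: injected activity must be > 0")
  norm_mask <- vois$liver | vois$lungs
  s <- sum(recon$data[norm_mask])
  if (s <= 0) stop("calibrate_activity: no counts in liver and lungs VOIs")
  out <- vol3d(recon$data * (injected_bq / s), recon$spacing, recon$origin)
  attr(out, "injected_bq") <- injected_bq
  attr(out, "calibration_factor") <- injected_bq / s
  out
}

#' Voxel dose-rate map from an activity map
#'
#' Deterministic substitutes for Monte Carlo transport:
#' `engine = "local"` deposits each decay's mean beta energy in its own voxel
#' (`rate = A * E_mean / m_voxel`); `engine = "kernel"` convolves the
#' activity with the radially symmetric 90Y dose-point kernel
#' ([y90_kernel_table()]), which agrees with the local engine in
#' charged-particle-equilibrium regions.
#'
#' @param activity a [vol3d()] activity map in Bq per voxel.
#' @param engine `"kernel"` (default) or `"local"`.
#' @param e_mean_mev mean beta energy per decay in MeV (default 0.9337).
#' @param density_g_ml tissue density (default 1.0, uniform).
#' @param kernel_table radial kernel table for the kernel engine.
#' @return a [vol3d()] dose-rate map in Gy/s.
#' @export
dose_rate <- function(activity, engine = c("kernel", "local"),
                      e_mean_mev = 0.9337, density_g_ml = 1.0,
                      kernel_table = y90_kernel_table()) {
  engine <- match.arg(engine)
  m_vox_kg <- prod(activity$spacing) / 1000 * density_g_ml / 1000
  e_j <- e_mean_mev * MEV_TO_J
  if (engine == "local") {
    vals <- activity$data * e_j / m_vox_kg
  } else {
    k <- build_dose_kernel(activity$spacing, kernel_table)
    vals <- conv3_cpp(activity$data, k) * e_j / m_vox_kg
  }
  out <- vol3d(vals, activity$spacing, activity$origin)
  attr(out, "engine") <- engine
  out
}

#' Integrate a dose-rate map over the full decay
#'
#' `D = rate0 * T_half / ln 2` per voxel (mono-exponential decay).
#'
#' @param rate a [vol3d()] dose-rate map (Gy/s).
#' @param decay a [decay_model()].
#' @return a [vol3d()] dose map (Gy) with the half-life recorded.
#' @export
integrate_decay <- function(rate, decay = decay_model()) {
  if (any(rate$data < 0)) stop("integrate_decay: negative dose rate")
  out <- vol3d(rate$data * decay$factor_s, rate$spacing, rate$origin)
  attr(out, "half_life_h") <- decay$half_life_h
  out
}

#' Mean absorbed dose over a VOI
#'
#' @param dose a [vol3d()] dose map.
#' @param mask nonempty logical array.
#' @return mean dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  if (!any(mask)) stop("mean_dose: empty VOI mask")
  mean(dose$data[mask])
}

#' Prescribed activity from a target dose
#'
#' `A [GBq] = prescription [Gy] / (dose per unit activity [Gy/GBq])`. The
#' ratio of prescribed activities between two reconstructions is independent
#' of the prescription value (dose is linear in activity).
#'
#' @param dose_per_gbq mean dose in the target VOI per GBq injected (Gy/GBq).
#' @param prescription_gy prescribed dose to the target VOI (Gy); no default
#'   is hard-coded in reports — 120 Gy is a common glass-sphere convention.
#' @return activity in GBq.
#' @export
prescribe_activity <- function(dose_per_gbq, prescription_gy) {
  if (dose_per_gbq <= 0) stop("prescribe_activity: dose per activity must be > 0")
  prescription_gy / dose_per_gbq
}

#' Difference in absorbed dose under alternate overlap assignment
#'
#' `DAD(VOI) = D_overlap_to_liver(VOI) - D_overlap_to_lungs(VOI)`: the mean
#' dose in `mask` when liver/lung shared voxels go to the liver minus the
#' mean dose when they go to the lungs.
#'
#' @param dose_liver_assign,dose_lungs_assign [vol3d()] dose maps computed
#'   with the two assignments.
#' @param mask_liver_assign,mask_lungs_assign the VOI mask under each
#'   assignment.
#' @return DAD in Gy.
#' @export
dad <- function(dose_liver_assign, dose_lungs_assign,
                mask_liver_assign, mask_lungs_assign) {
  mean_dose(dose_liver_assign, mask_liver_assign) -
    mean_dose(dose_lungs_assign, mask_lungs_assign)
}
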