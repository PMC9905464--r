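#' Planning comparison metrics
#'
#' The four comparison quantities between the conventional (3D) and
#' motion-compensated (3Dcomp) reconstructions:
#' percentage dose difference `PDD = (D_3Dcomp - D_3D) / D_3D * 100`,
#' lung shunt fraction `LSF = C_lungs / (C_lungs + C_liver) * 100`,
#' tumor-to-normal ratio `TN = (C_T / V_T) / (C_HL / V_HL)` (densities
#' assumed equal, volumes stand in for masses), and percentage activity
#' difference `PDA = (A_3Dcomp - A_3D) / A_3D * 100`.
#'
#' @param d_3dcomp,d_3d mean absorbed doses (Gy); `d_3d` must be nonzero.
#' @return percentage (vectorized).
#' @export
pdd <- function(d_3dcomp, d_3d) {
  if (any(d_3d == 0, na.rm = TRUE)) stop("pdd: undefined for zero 3D dose")
  (d_3dcomp - d_3d) / d_3d * 100
}

#' @rdname pdd
#' @param c_lungs,c_liver reconstructed counts in lungs and liver.
#' @export
lsf <- function(c_lungs, c_liver) {
  if (any(c_lungs + c_liver <= 0, na.rm = TRUE)) stop("lsf: no counts in lungs + liver")
  c_lungs / (c_lungs + c_liver) * 100
}

#' @rdname pdd
#' @param c_t,v_t,c_hl,v_hl counts and volumes of all tumors and the healthy
#'   liver (volumes in any common unit).
#' @export
tn_ratio <- function(c_t, v_t, c_hl, v_hl) {
  if (any(c(c_t, v_t, c_hl, v_hl) <= 0)) stop("tn_ratio: all inputs must be > 0")
  (c_t / v_t) / (c_hl / v_hl)
}

#' @rdname pdd
#' @param a_3dcomp,a_3d prescribed activities (GBq); `a_3d` must be nonzero.
#' @export
pda <- function(a_3dcomp, a_3d) {
  if (any(a_3d == 0, na.rm = TRUE)) stop("pda: undefined for zero 3D activity")
  (a_3dcomp - a_3d) / a_3d * 100
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and 1.96-sd limits of agreement for paired series, with a
#' Shapiro-Wilk normality check of the differences (limits are reported for
#' information only when the differences are not normal).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list: `mean_diff`, `sd_diff`, `loa` (lower/upper),
#'   `pairs` (per-pair means and differences), `shapiro_p` (NA for n < 3 or
#'   constant differences).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("bland_altman: length mismatch")
  if (length(a) < 2) stop("bland_altman: need at least 2 pairs")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d); sdd <- stats::sd(d)
  sh <- if (length(d) >= 3 && stats::sd(d) > 0)
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  else NA_real_
  list(mean_diff = md, sd_diff = sdd,
       loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
       pairs = data.frame(mean = m, diff = d), shapiro_p = sh)
}

# mutual information between two discretized vectors
mutual_information <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1L, 1L), bins)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) / length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(b)
  nz <- joint > 0
  outer_p <- as.vector(outer(pa, pb))
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Estimate breathing amplitude by local rigid registration
#'
#' Translation-only registration of `moving` onto `fixed`, restricted to the
#' (dilated) liver mask, maximizing histogram-based mutual information
#' (default 32 bins) over the 3D translation; the amplitude is the Euclidean
#' norm of the translation in mm. Initialization is the masked intensity
#' centroid difference. A mask smaller than `min_voxels` is declared
#' not-estimable (`NA` with attribute `reason`), mirroring the clinical case
#' of a lesion too small to register.
#'
#' @param fixed,moving [vol3d()] images sharing geometry (e.g. exhale and
#'   inhale reconstructions).
#' @param mask logical array (liver or lesion VOI).
#' @param bins histogram bins for mutual information.
#' @param dilate_vox mask dilation half-width in voxels; the region must
#'   cover the full breathing excursion or the optimum is biased toward
#'   small translations (default 5 voxels, ~22 mm at the acquisition
#'   spacing, comfortably above the clinical amplitude range).
#' @param min_voxels minimum mask size for a trustworthy registration.
#' @return amplitude in mm, with attribute `translation_mm`.
#' @export
estimate_amplitude <- function(fixed, moving, mask, bins = 32L,
                               dilate_vox = 5L, min_voxels = 30L) {
  stopifnot_same_geometry(fixed, moving, "registration images")
  if (!any(mask)) stop("estimate_amplitude: empty mask")
  if (sum(mask) < min_voxels) {
    out <- NA_real_
    attr(out, "reason") <- "too small volume for registration"
    return(out)
  }
  reg <- dilate_mask(mask, dilate_vox)
  sp <- fixed$spacing
  fvals <- fixed$data[reg]
  com <- function(v) {
    w <- v$data * reg
    s <- sum(w)
    if (s == 0) return(c(0, 0, 0))
    idx <- which(reg, arr.ind = TRUE)
    colSums(idx * w[reg]) / s
  }
  t0 <- com(moving) - com(fixed)
  obj <- function(t_vox) {
    mv <- translate3_cpp(moving$data, t_vox[1], t_vox[2], t_vox[3])
    -mutual_information(fvals, mv[reg], bins)
  }
  fit <- stats::optim(t0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-9))
  t_mm <- fit$par * sp
  out <- sqrt(sum(t_mm^2))
  attr(out, "translation_mm") <- t_mm
  out
}

# 6-neighborhood border voxels of a logical mask
mask_border <- function(mask) {
  d <- dim(mask)
  shifted_all_in <- array(TRUE, d)
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    sh <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (s == 1L) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1L) }
    else { idx_dst[[axis]] <- 1:(n - 1L); idx_src[[axis]] <- 2:n }
    sh <- do.call(`[<-`, c(list(sh), idx_dst, list(do.call(`[`, c(list(mask), idx_src)))))
    shifted_all_in <- shifted_all_in & sh
  }
  mask & !shifted_all_in
}

#' Geometric tumor predictors
#'
#' The seven per-lesion predictors of motion sensitivity, plus each divided
#' by the lesion volume:
#' (1) volume (mL); (2) minimum and (3) mean distance from the lesion border
#' to the liver border (mm); (4) CC gap between the most cranial lesion voxel
#' and the most cranial liver voxel in the lesion's axial footprint (mm);
#' (5) lesion CC motion amplitude (mm, supplied); (6) minimum distance from
#' the lesion center of mass to the liver border (mm); (7) the same
#' restricted to the CC axis (border voxels in the center-of-mass column).
#' A lesion (partly) outside the liver is flagged, not rejected.
#'
#' @param lesion,liver logical arrays.
#' @param spacing voxel spacing mm.
#' @param cc_amplitude_mm lesion CC motion amplitude (mm), from registration
#'   or ground truth.
#' @param cc_gap `"footprint"` (default) or `"global"`: reference liver top
#'   for feature (4).
#' @return named list: `features` (length 7), `features_per_volume`,
#'   `outside_liver` flag.
#' @export
tumor_features <- function(lesion, liver, spacing, cc_amplitude_mm = NA_real_,
                           cc_gap = c("footprint", "global")) {
  cc_gap <- match.arg(cc_gap)
  if (!any(lesion) || !any(liver)) stop("tumor_features: empty mask")
  spacing <- as.numeric(spacing)
  vol_ml <- sum(lesion) * prod(spacing) / 1000
  border <- mask_border(liver)
  bco <- mask_coords_mm(border, spacing)
  lb <- mask_border(lesion)
  lco <- mask_coords_mm(lb, spacing)
  dists <- min_dist_to_set_cpp(lco, bco)

  # feature 4: CC gap, lesion top vs liver top over the lesion footprint
  les_idx <- which(lesion, arr.ind = TRUE)
  liv_idx <- which(liver, arr.ind = TRUE)
  les_top <- max(les_idx[, 3])
  if (cc_gap == "footprint") {
    foot <- unique(les_idx[, 1:2, drop = FALSE])
    key <- paste(liv_idx[, 1], liv_idx[, 2])
    fkey <- paste(foot[, 1], foot[, 2])
    liv_top <- max(liv_idx[key %in% fkey, 3])
  } else {
    liv_top <- max(liv_idx[, 3])
  }
  f4 <- (liv_top - les_top) * spacing[3]

  com_mm <- colMeans(mask_coords_mm(lesion, spacing))
  f6 <- min_dist_to_set_cpp(matrix(com_mm, 1), bco)[1]
  # feature 7: border voxels in the center-of-mass column, CC distance only
  com_vox <- pmin(pmax(round(com_mm / spacing + 0.5), 1), dim(lesion))
  bidx <- which(border, arr.ind = TRUE)
  incol <- bidx[, 1] == com_vox[1] & bidx[, 2] == com_vox[2]
  f7 <- if (any(incol)) {
    min(abs((bidx[incol, 3] - 0.5) * spacing[3] - com_mm[3]))
  } else {
    f6
  }
  feats <- c(volume_ml = vol_ml,
             min_border_dist_mm = min(dists),
             mean_border_dist_mm = mean(dists),
             cc_gap_top_mm = f4,
             cc_amplitude_mm = cc_amplitude_mm,
             com_border_dist_mm = f6,
             com_border_cc_dist_mm = f7)
  list(features = feats, features_per_volume = feats / vol_ml,
       outside_liver = any(lesion & !liver))
}

#' Paired comparison testing suite
#'
#' Applies the planning statistics protocol to two paired series: Shapiro-
#' Wilk normality on each series, then a paired t test if both are normal at
#' `alpha` or a paired Wilcoxon test otherwise (constant series force the
#' Wilcoxon branch and are flagged). Optionally computes Spearman rank
#' correlations (raw p-values) between a target vector and a set of
#' predictors.
#'
#' @param a,b paired numeric series (n >= 3).
#' @param predictors optional data.frame of predictor columns.
#' @param target optional numeric vector correlated against `predictors`
#'   (e.g. per-lesion tumor PDD).
#' @param alpha normality gate (default 0.05).
#' @return list: `normality` (p-values), `branch` (`"t"` or `"wilcoxon"`),
#'   `statistic`, `p_value`, `mean_diff`, `flags`, `spearman`
#'   (data.frame of rho and p per predictor, when requested).
#' @export
stats_suite <- function(a, b, predictors = NULL, target = NULL, alpha = 0.05) {
  if (length(a) != length(b)) stop("stats_suite: length mismatch")
  if (length(a) < 3) stop("stats_suite: need n >= 3")
  flags <- character()
  shap <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  pa <- shap(a); pb <- shap(b)
  if (is.na(pa) || is.na(pb)) flags <- c(flags, "constant series: normality undefined, Wilcoxon forced")
  normal <- !is.na(pa) && !is.na(pb) && pa >= alpha && pb >= alpha
  d <- a - b
  if (all(d == 0)) {
    ht <- list(statistic = 0, p.value = 1)
    branch <- "wilcoxon"
    flags <- c(flags, "all paired differences zero")
  } else if (normal) {
    ht <- stats::t.test(a, b, paired = TRUE)
    branch <- "t"
  } else {
    ht <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    branch <- "wilcoxon"
  }
  out <- list(normality = c(a = pa, b = pb), branch = branch,
              statistic = unname(ht$statistic), p_value = ht$p.value,
              mean_diff = mean(d), flags = flags)
  if (!is.null(predictors) && !is.null(target)) {
    rows <- lapply(names(predictors), function(nm) {
      ct <- suppressWarnings(
        stats::cor.test(target, predictors[[nm]], method = "spearman",
                        exact = FALSE))
      data.frame(predictor = nm, rho = unname(ct$estimate),
                 p_value = ct$p.value)
    })
    out$spearman <- do.call(rbind, rows)
  }
  out
}
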