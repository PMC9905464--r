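#' OSEM reconstruction configuration
#'
#' Defaults follow the clinical protocol: 15 subsets and 15 full iterations
#' (each iteration cycles all subsets, i.e. 225 sub-iterations), no
#' post-reconstruction filtering. The reconstruction grid is the phantom /
#' attenuation-map grid.
#'
#' @param n_subsets number of ordered subsets (default 15).
#' @param n_iterations number of full OSEM iterations (default 15).
#' @param epsilon nonnegativity/zero-divide guard.
#' @param dew_k dual-energy-window scaling factor; `NULL` means the Jaszczak
#'   convention `(primary width / scatter width) / 2` from the acquisition
#'   windows.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(n_subsets = 15L, n_iterations = 15L,
                         epsilon = 1e-10, dew_k = NULL) {
  if (n_iterations < 1) stop("recon_config: n_iterations must be >= 1")
  if (n_subsets < 1) stop("recon_config: n_subsets must be >= 1")
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 epsilon = epsilon, dew_k = dew_k),
            class = "recon_config")
}

#' Dual-energy-window scatter estimate
#'
#' Estimates scatter in the primary window as `k` times the scatter-window
#' counts, with `k = (primary width / scatter width) / 2` by default
#' (Jaszczak convention; 28.1 keV / 12 keV / 2 = 1.171 for the default
#' windows). The estimate is clipped at the observed primary counts when
#' supplied.
#'
#' @param scatter_counts scatter-window counts (any array).
#' @param acq an [acquisition_spec()] (provides the window widths).
#' @param k override for the scaling factor.
#' @param primary_counts optional primary-window counts used for clipping.
#' @return scatter estimate, same shape as `scatter_counts`.
#' @export
dew_scatter_estimate <- function(scatter_counts, acq, k = NULL,
                                 primary_counts = NULL) {
  ww <- window_widths_kev(acq)
  if (any(ww <= 0)) stop("dew_scatter_estimate: zero-width energy window")
  if (is.null(k)) k <- (ww["primary"] / ww["scatter"]) / 2
  est <- k * scatter_counts
  if (!is.null(primary_counts)) est <- pmin(est, primary_counts)
  est
}

#' OSEM reconstruction
#'
#' Ordered-subset expectation maximization with the attenuated,
#' depth-dependent-PSF projector in the system model and an optional additive
#' scatter estimate in the forward denominator. Voxels with zero sensitivity
#' (outside every subset's field of view) are excluded from the update and
#' set to zero; the count is recorded in attribute `n_zero_sensitivity`.
#' No post-reconstruction filtering is applied.
#'
#' @param projections primary-window counts, array `[n_u, n_v, n_angles]`.
#' @param angles_deg projection angles (degrees).
#' @param mu attenuation map ([vol3d()]) defining the reconstruction grid.
#' @param acq an [acquisition_spec()].
#' @param config a [recon_config()].
#' @param scatter additive scatter estimate, same shape as `projections`
#'   (or `NULL`).
#' @param method_tag provenance tag stored on the result.
#' @param x_init optional initial image (array); default uniform ones.
#' @return a [vol3d()] reconstruction (counts per voxel) with provenance
#'   attributes.
#' @export
osem <- function(projections, angles_deg, mu, acq, config = recon_config(),
                 scatter = NULL, method_tag = "3D", x_init = NULL) {
  if (any(projections < 0) || any(!is.finite(projections)))
    stop("osem: projections must be nonnegative and finite")
  na <- dim(projections)[3]
  if (na != length(angles_deg)) stop("osem: angles/projections mismatch")
  eps <- config$epsilon
  nsub <- min(config$n_subsets, na)
  subsets <- lapply(seq_len(nsub), function(s) seq(s, na, by = nsub))

  sens <- vector("list", nsub)
  ones <- matrix(1, dim(projections)[1], dim(projections)[2])
  for (s in seq_len(nsub)) {
    acc <- 0
    for (a in subsets[[s]])
      acc <- acc + back_project(ones, mu, acq, angles_deg[a])$data
    sens[[s]] <- acc
  }
  total_sens <- Reduce(`+`, sens)
  dead <- total_sens <= eps
  x <- if (is.null(x_init)) array(1, dim(mu$data)) else x_init
  x[dead] <- 0

  for (it in seq_len(config$n_iterations)) {
    for (s in seq_len(nsub)) {
      bp <- 0
      for (a in subsets[[s]]) {
        fp <- forward_project(vol3d(x, mu$spacing, mu$origin), mu, acq,
                              angles_deg[a])
        if (!is.null(scatter)) fp <- fp + scatter[, , a]
        ratio <- projections[, , a] / pmax(fp, eps)
        ratio[projections[, , a] == 0] <- 0
        bp <- bp + back_project(ratio, mu, acq, angles_deg[a])$data
      }
      upd <- bp / pmax(sens[[s]], eps)
      upd[sens[[s]] <= eps] <- 1
      x <- x * upd
      x[dead] <- 0
    }
  }
  out <- vol3d(x, mu$spacing, mu$origin)
  attr(out, "method") <- method_tag
  attr(out, "n_updates") <- config$n_iterations * nsub
  attr(out, "n_zero_sensitivity") <- sum(dead)
  out
}

#' Poisson log-likelihood of an image given projections
#'
#' Evaluates the Poisson log-likelihood (up to the data-dependent constant)
#' of projection data under the projector's forward model; used as the MLEM
#' monotonicity oracle.
#'
#' @inheritParams osem
#' @param x a [vol3d()] image.
#' @return scalar log-likelihood.
#' @export
osem_loglik <- function(x, projections, angles_deg, mu, acq, scatter = NULL) {
  ll <- 0
  for (a in seq_along(angles_deg)) {
    q <- forward_project(x, mu, acq, angles_deg[a])
    if (!is.null(scatter)) q <- q + scatter[, , a]
    y <- projections[, , a]
    pos <- q > 0
    ll <- ll + sum(y[pos] * log(q[pos]) - q[pos]) - sum(q[!pos])
    if (any(y[!pos] > 0)) ll <- -Inf
  }
  ll
}

#' Conventional (ungated) 3D reconstruction from list-mode data
#'
#' Bins all events regardless of phase, forms the dual-energy-window scatter
#' estimate and runs OSEM.
#'
#' @param lm a [acquire_listmode()] result.
#' @param mu attenuation map.
#' @param acq acquisition spec.
#' @param config a [recon_config()].
#' @return a [vol3d()] with method tag `"3D"`.
#' @export
reconstruct_3d <- function(lm, mu, acq, config = recon_config()) {
  pr <- ungated_projections(lm)
  scat <- dew_scatter_estimate(pr$scatter, acq, config$dew_k, pr$primary)
  osem(pr$primary, lm$angles_deg, mu, acq, config, scatter = scat,
       method_tag = "3D")
}

#' Gated 4D reconstruction
#'
#' Reconstructs each respiratory phase independently from its gated
#' projections, using the single attenuation map for every phase. Empty
#' phases yield a zero image with a warning.
#'
#' @param lm a [acquire_listmode()] result.
#' @param event_labels 0-based phase label per event.
#' @param n_phases number of phases.
#' @inheritParams reconstruct_3d
#' @return list of [vol3d()] reconstructions, method tag `"4Dgated"`.
#' @export
reconstruct_gated_4d <- function(lm, event_labels, n_phases, mu, acq,
                                 config = recon_config()) {
  gated <- bin_listmode(lm, event_labels, n_phases)
  out <- vector("list", n_phases)
  for (p in seq_len(n_phases)) {
    if (sum(gated[[p]]$primary) == 0) {
      warning(sprintf("phase %d holds no events; zero image", p - 1L))
      out[[p]] <- vol3d(array(0, dim(mu$data)), mu$spacing, mu$origin)
      attr(out[[p]], "method") <- "4Dgated"
      next
    }
    scat <- dew_scatter_estimate(gated[[p]]$scatter, acq, config$dew_k,
                                 gated[[p]]$primary)
    out[[p]] <- osem(gated[[p]]$primary, lm$angles_deg, mu, acq, config,
                     scatter = scat, method_tag = "4Dgated")
    attr(out[[p]], "phase") <- p - 1L
  }
  out
}

#' Inter-phase 2D affine registration of gated projections
#'
#' For every phase other than the reference and every projection angle,
#' estimates a 6-parameter 2D affine transform mapping that phase's
#' (count-normalized, smoothed) projection onto the reference phase's, by
#' Nelder-Mead minimization of the mean squared error. Translation is
#' initialized from the count centroid difference. A failed optimization
#' falls back to the identity with a warning. Because the true transforms
#' vary smoothly with angle while per-angle fits on gated (1/n_phases of
#' the counts) projections are noisy, the fitted parameters are optionally
#' smoothed across angles with a circular moving average; leaving this off
#' blurs the corrected events and biases small structures (see the methods
#' vignette).
#'
#' @param gated a [bin_listmode()] result.
#' @param ref 0-based reference phase index.
#' @param smooth_fwhm_bins Gaussian smoothing FWHM (detector bins) applied to
#'   both images before matching.
#' @param smooth_angles odd window (in angles, circular) for parameter
#'   smoothing; 1 disables it.
#' @return array `[n_phases, n_angles, 6]` of parameters
#'   `(m11, m12, m21, m22, tu, tv)` in bin units (identity rows for the
#'   reference phase).
#' @export
register_phases_2d_affine <- function(gated, ref, smooth_fwhm_bins = 3,
                                      smooth_angles = 5L) {
  n_phases <- length(gated)
  if (ref < 0 || ref >= n_phases) stop("register_phases_2d_affine: ref out of range")
  na <- dim(gated[[1]]$primary)[3]
  out <- array(rep(c(1, 0, 0, 1, 0, 0), each = n_phases * na),
               c(n_phases, na, 6))
  sig <- smooth_fwhm_bins / 2.354820045
  prep <- function(img) {
    s <- sum(img)
    if (s > 0) img <- img / s
    blur2_cpp(img, sig, sig)
  }
  centroid <- function(img) {
    s <- sum(img)
    if (s == 0) return(c(0, 0))
    c(sum(row(img) * img), sum(col(img) * img)) / s
  }
  for (p in seq_len(n_phases)) {
    if (p - 1L == ref) next
    for (a in seq_len(na)) {
      fixed <- prep(gated[[ref + 1L]]$primary[, , a])
      moving <- prep(gated[[p]]$primary[, , a])
      if (sum(fixed) == 0 || sum(moving) == 0) {
        warning(sprintf("empty projection (phase %d, angle %d); identity kept",
                        p - 1L, a))
        next
      }
      t0 <- centroid(moving) - centroid(fixed)
      par0 <- c(1, 0, 0, 1, t0)
      obj <- function(par) mean((affine_resample2_cpp(moving, par) - fixed)^2)
      fit <- tryCatch(
        stats::optim(par0, obj, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("registration failed (phase %d, angle %d); identity kept",
                        p - 1L, a))
      } else {
        out[p, a, ] <- fit$par
      }
    }
  }
  if (smooth_angles > 1L && na >= smooth_angles) {
    half <- (as.integer(smooth_angles) - 1L) %/% 2L
    for (p in seq_len(n_phases)) {
      if (p - 1L == ref) next
      for (q in 1:6) {
        v <- out[p, , q]
        sm <- vapply(seq_len(na), function(a) {
          idx <- ((a - half - 1L):(a + half - 1L)) %% na + 1L
          mean(v[idx])
        }, 0)
        out[p, , q] <- sm
      }
    }
  }
  out
}

#' Motion-compensated 3D reconstruction (3Dcomp)
#'
#' Applies each phase's per-angle affine transform to the list-mode events
#' (detector coordinates mapped into the reference-phase frame, bilinear
#' count splatting), rebins all corrected events into a single projection set
#' and reconstructs it with OSEM — using all counts, so noise is comparable
#' to the conventional 3D reconstruction. Events mapped off the detector are
#' dropped and counted in attribute `n_dropped`.
#'
#' @param lm a [acquire_listmode()] result.
#' @param event_labels 0-based phase label per event.
#' @param transforms a [register_phases_2d_affine()] result.
#' @param ref 0-based reference phase.
#' @param mu attenuation map at the reference phase.
#' @param acq acquisition spec.
#' @param config a [recon_config()].
#' @return a [vol3d()] with method tag `"3Dcomp"`.
#' @export
reconstruct_3dcomp <- function(lm, event_labels, transforms, ref, mu, acq,
                               config = recon_config()) {
  ev <- lm$events
  n_phases <- dim(transforms)[1]
  nu <- lm$det_dim[1]; nv <- lm$det_dim[2]; na <- length(lm$angles_deg)
  cu <- (nu - 1) / 2; cv <- (nv - 1) / 2
  prim <- array(0, c(nu, nv, na))
  scat <- array(0, c(nu, nv, na))
  dropped <- 0L
  lost <- 0
  for (a in seq_len(na)) {
    in_a <- ev$proj == a
    for (p in seq_len(n_phases)) {
      sel <- in_a & event_labels == (p - 1L)
      if (!any(sel)) next
      u <- ev$iu[sel] - 1; v <- ev$iv[sel] - 1
      if (p - 1L != ref) {
        par <- transforms[p, a, ]
        A <- matrix(par[1:4], 2, byrow = TRUE)
        rhs <- rbind(u - cu - par[5], v - cv - par[6])
        xy <- solve(A, rhs)                    # ref-frame centered coords
        u <- xy[1, ] + cu; v <- xy[2, ] + cv
      }
      for (w in 1:2) {
        ww <- ev$window[sel] == w
        if (!any(ww)) next
        sp <- splat_events_cpp(u[ww], v[ww], nu, nv)
        if (w == 1) prim[, , a] <- prim[, , a] + sp$counts
        else scat[, , a] <- scat[, , a] + sp$counts
        dropped <- dropped + sp$dropped
        lost <- lost + (sum(ww) - sp$placed)
      }
    }
  }
  scat_est <- dew_scatter_estimate(scat, acq, config$dew_k, prim)
  out <- osem(prim, lm$angles_deg, mu, acq, config, scatter = scat_est,
              method_tag = "3Dcomp")
  attr(out, "reference_phase") <- ref
  attr(out, "n_dropped") <- dropped          # events fully off the detector
  attr(out, "lost_weight") <- lost           # total clipped splat weight
  attr(out, "corrected_counts") <- sum(prim) + sum(scat)
  out
}
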