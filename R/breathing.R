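#' Rebin list-mode events into time-binned detector features
#'
#' Preprocessing for the data-driven respiratory signal: the scan is cut into
#' time bins of width `dt` and each bin's events are histogrammed on a coarse
#' detector grid (restricted to the projection active at that time). Rows are
#' the per-time-bin feature vectors fed to the Laplacian eigenmap.
#'
#' @param lm a [acquire_listmode()] result.
#' @param dt time bin width in seconds (default 0.5).
#' @param coarse coarse detector grid (default 16x16).
#' @return object of class `lm_features`: `counts` (raw histogram matrix,
#'   time bins x cells), `time` (bin centers, s), `proj` (projection index per
#'   bin), `cell_v` (coarse v coordinate per cell), `dt`. Empty time bins are
#'   retained as zero rows.
#' @export
rebin_listmode_features <- function(lm, dt = 0.5, coarse = c(16, 16)) {
  if (dt <= 0) stop("rebin_listmode_features: dt must be > 0")
  if (lm$scan_time_s < dt) stop("rebin_listmode_features: scan shorter than dt")
  ev <- lm$events
  nt <- ceiling(lm$scan_time_s / dt - 1e-9)
  tb <- pmin(pmax(floor(ev$t / dt) + 1L, 1L), nt)
  cu <- pmin(ceiling(ev$iu / lm$det_dim[1] * coarse[1]), coarse[1])
  cv <- pmin(ceiling(ev$iv / lm$det_dim[2] * coarse[2]), coarse[2])
  cell <- cu + (cv - 1L) * coarse[1]
  ncell <- prod(coarse)
  counts <- matrix(tabulate(tb + (cell - 1L) * nt, nbins = nt * ncell),
                   nrow = nt, ncol = ncell)
  tmid <- (seq_len(nt) - 0.5) * dt
  proj <- pmin(floor(tmid / lm$acq$time_per_projection_s) + 1L,
               length(lm$angles_deg))
  structure(list(counts = counts, time = tmid, proj = as.integer(proj),
                 cell_v = rep(seq_len(coarse[2]), each = coarse[1]),
                 coarse = coarse, dt = dt, n_events = nrow(ev)),
            class = "lm_features")
}

# normalized + per-projection centered feature rows
normalize_features <- function(feat, smooth_bins = 1L) {
  x <- feat$counts
  rs <- rowSums(x)
  x <- x / pmax(rs, 1)                         # shape; zero rows stay zero
  if (smooth_bins > 1L) {                      # light temporal smoothing
    k <- rep(1 / smooth_bins, smooth_bins)
    x <- apply(x, 2, function(col) stats::filter(col, k, sides = 2))
    x[is.na(x)] <- 0
  }
  for (pr in unique(feat$proj)) {
    sel <- feat$proj == pr
    x[sel, ] <- sweep(x[sel, , drop = FALSE], 2,
                      colMeans(x[sel, , drop = FALSE]))
  }
  x
}

# connected components of a symmetric adjacency (list of integer neighbor
# vectors); returns component id per node
graph_components <- function(nbrs) {
  n <- length(nbrs)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, nbrs[[v]][comp[nbrs[[v]]] == 0L])
    }
  }
  comp
}

#' Extract the respiratory signal by Laplacian eigenmaps
#'
#' Builds a Gaussian-kernel k-nearest-neighbor graph on the normalized,
#' per-projection-centered feature rows and returns the first nontrivial
#' eigenvector of the normalized graph Laplacian as the 1D respiratory
#' signal. The kernel bandwidth is the median k-NN distance. The sign is
#' fixed so that the signal correlates positively with the axial (cranial)
#' count-centroid surrogate. If the graph is disconnected, k is doubled with
#' a warning (error if it stays disconnected). Identical rows yield a flat
#' signal with `degenerate = TRUE`.
#'
#' @param feat a [rebin_listmode_features()] result.
#' @param k_neighbors neighborhood size (default 20).
#' @param smooth_bins temporal feature smoothing window (bins; default 1 =
#'   off — temporal smoothing makes graph neighbors temporal rather than
#'   phase-similar and destroys the embedding).
#' @return object of class `resp_signal`: `time`, `amplitude`, `dt`, `proj`,
#'   `degenerate`.
#' @export
laplacian_eigenmap_signal <- function(feat, k_neighbors = 20L,
                                      smooth_bins = 1L) {
  x <- normalize_features(feat, smooth_bins)
  n <- nrow(x)
  if (n < k_neighbors + 1L)
    stop("laplacian_eigenmap_signal: need at least k_neighbors + 1 rows")
  sig <- list(time = feat$time, dt = feat$dt, proj = feat$proj)

  d2 <- as.matrix(stats::dist(x))^2
  if (max(d2) <= 0) {
    sig$amplitude <- rep(0, n); sig$degenerate <- TRUE
    class(sig) <- "resp_signal"
    return(sig)
  }

  k <- as.integer(k_neighbors)
  repeat {
    nn <- apply(d2, 1, function(r) order(r)[2:(k + 1L)])  # cols = nodes
    nbrs <- lapply(seq_len(n), function(i) nn[, i])
    # symmetrize
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) adj[i, nbrs[[i]]] <- TRUE
    adj <- adj | t(adj)
    nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
    comp <- graph_components(nbrs)
    if (max(comp) == 1L) break
    if (k >= n - 1L)
      stop("laplacian_eigenmap_signal: k-NN graph disconnected at k = n-1")
    k <- min(2L * k, n - 1L)
    warning(sprintf("k-NN graph disconnected; increasing k to %d", k))
  }
  knn_d <- sqrt(d2)[adj]
  sigma <- stats::median(knn_d)
  if (sigma <= 0) sigma <- 1
  W <- matrix(0, n, n)
  W[adj] <- exp(-d2[adj] / (2 * sigma^2))
  deg <- rowSums(W)
  dis <- 1 / sqrt(pmax(deg, 1e-12))
  M <- W * outer(dis, dis)                     # D^-1/2 W D^-1/2

  if (n <= 1200L) {
    e <- eigen(M, symmetric = TRUE)
    v <- e$vectors[, 2]
  } else {
    v <- power_iter_second(M, sqrt(deg))
  }
  f <- dis * v                                 # generalized eigenvector
  # sign convention: positive correlation with cranial count centroid
  surro <- axial_centroid_surrogate(feat)
  if (stats::sd(f) > 0 && stats::sd(surro) > 0 &&
      stats::cor(f, surro) < 0) f <- -f
  sig$amplitude <- f
  sig$degenerate <- FALSE
  class(sig) <- "resp_signal"
  sig
}

# deflated power iteration for the second eigenvector of symmetric M whose
# top eigenvector is known up to scale (v1)
power_iter_second <- function(M, v1, iters = 500L, tol = 1e-9) {
  v1 <- v1 / sqrt(sum(v1^2))
  n <- nrow(M)
  set.seed(0L)
  v <- stats::rnorm(n)
  v <- v - sum(v * v1) * v1
  v <- v / sqrt(sum(v^2))
  shift <- 1                                    # M + I is PSD (eigs in [0,2])
  for (it in seq_len(iters)) {
    w <- as.vector(M %*% v) + shift * v
    w <- w - sum(w * v1) * v1
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sum(abs(w - v)) < tol * n) { v <- w; break }
    v <- w
  }
  v
}

# per-time-bin axial count centroid (cranial surrogate), per-projection
# centered
axial_centroid_surrogate <- function(feat) {
  tot <- rowSums(feat$counts)
  cen <- as.vector(feat$counts %*% feat$cell_v) / pmax(tot, 1)
  for (pr in unique(feat$proj)) {
    sel <- feat$proj == pr
    cen[sel] <- cen[sel] - mean(cen[sel])
  }
  cen
}

#' Split the respiratory signal into phases
#'
#' Detects breathing cycles from upward zero crossings of the smoothed,
#' median-centered signal and divides each cycle into `n_phases` equal-time
#' bins. Time bins before the first (after the last) crossing are labeled by
#' extrapolating with the median cycle length. If fewer than two crossings
#' are found, falls back to amplitude-quantile binning with a warning.
#'
#' @param signal a [laplacian_eigenmap_signal()] result (or any list with
#'   `time`, `amplitude`, `dt`).
#' @param n_phases number of phases (default 8).
#' @param lm optional [acquire_listmode()] result; when given, per-event
#'   labels are returned as well.
#' @param smooth_s smoothing window in seconds before crossing detection.
#' @return list: `time_labels` (0-based phase per time bin), `event_labels`
#'   (if `lm` supplied), `n_phases`, `method` ("cycles" or "quantiles").
#' @export
assign_phases <- function(signal, n_phases = 8L, lm = NULL, smooth_s = 1.5) {
  n_phases <- as.integer(n_phases)
  s <- signal$amplitude
  if (any(!is.finite(s))) stop("assign_phases: signal must be finite")
  nt <- length(s)
  if (n_phases == 1L) {
    labs <- rep(0L, nt)
    return(finish_phase_assignment(labs, signal, n_phases, "single", lm))
  }
  win <- max(1L, round(smooth_s / signal$dt))
  if (win > 1L) {
    sm <- stats::filter(s, rep(1 / win, win), sides = 2)
    sm[is.na(sm)] <- s[is.na(sm)]
    s <- as.numeric(sm)
  }
  s <- s - stats::median(s)
  up <- which(s[-nt] < 0 & s[-1] >= 0) + 1L     # upward crossing bin indices
  if (length(up) < 2L) {
    warning("assign_phases: no breathing cycles detected; falling back to amplitude quantiles")
    qs <- stats::quantile(s, probs = seq(0, 1, length.out = n_phases + 1L))
    labs <- pmin(pmax(findInterval(s, qs[-c(1, n_phases + 1L)]), 0L),
                 n_phases - 1L)
    return(finish_phase_assignment(as.integer(labs), signal, n_phases,
                                   "quantiles", lm))
  }
  # sub-bin crossing times by linear interpolation (dt often divides the
  # breathing period, so bin-quantized crossings would carry a constant
  # phase offset)
  i0 <- up - 1L
  tcross <- signal$time[i0] + s[i0] / (s[i0] - s[up]) * signal$dt
  med_cyc <- stats::median(diff(tcross))
  # anchor cycle starts on the signal maximum (end-exhale), which is the
  # physiological phase origin. Per-cycle peak picking is unreliable on the
  # flat-topped exhale-dwell waveform, so a single global offset from the
  # crossings to the extremum is estimated from the phase of the signal's
  # fundamental frequency component.
  w <- 2 * pi * signal$time / med_cyc
  phi <- med_cyc / (2 * pi) *
    atan2(sum(s * sin(w)), sum(s * cos(w)))     # fundamental peak time mod T
  delta <- (phi - tcross) %% med_cyc
  delta[delta > med_cyc / 2] <- delta[delta > med_cyc / 2] - med_cyc
  tcross <- tcross + stats::median(delta)
  # extend boundaries to cover the whole scan with median-length cycles
  lo <- tcross[1]; hi <- tcross[length(tcross)]
  n_pre <- max(0L, ceiling((lo - min(signal$time)) / med_cyc))
  n_post <- max(1L, ceiling((max(signal$time) - hi) / med_cyc) + 1L)
  pre <- if (n_pre > 0) lo - (n_pre:1) * med_cyc else numeric()
  post <- hi + seq_len(n_post) * med_cyc
  bounds <- c(pre, tcross, post)
  label_at <- function(times) {
    cyc <- findInterval(times, bounds, rightmost.closed = FALSE)
    cyc <- pmin(pmax(cyc, 1L), length(bounds) - 1L)
    frac <- (times - bounds[cyc]) / (bounds[cyc + 1L] - bounds[cyc])
    # centered bins: phase p covers [(p-1/2), (p+1/2))/n of the cycle
    as.integer(round(pmin(pmax(frac, 0), 1) * n_phases) %% n_phases)
  }
  finish_phase_assignment(label_at(signal$time), signal, n_phases, "cycles",
                          lm, label_at)
}

# events are labeled from their exact timestamps through the detected cycle
# boundaries when available (avoids time-bin quantization); quantile/single
# fallbacks label events by their time bin
finish_phase_assignment <- function(time_labels, signal, n_phases, method, lm,
                                    label_at = NULL) {
  out <- list(time_labels = time_labels, n_phases = n_phases, method = method)
  if (!is.null(lm)) {
    if (!is.null(label_at)) {
      out$event_labels <- label_at(lm$events$t)
    } else {
      tb <- pmin(pmax(floor(lm$events$t / signal$dt) + 1L, 1L),
                 length(time_labels))
      out$event_labels <- time_labels[tb]
    }
  }
  out
}

#' Permutation null test for signal structure
#'
#' Tests whether a respiratory signal carries temporal structure by comparing
#' its absolute lag-1 autocorrelation against a null distribution obtained by
#' randomly permuting the time order.
#'
#' @param signal a `resp_signal`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `statistic` and `p_value`.
#' @export
signal_permutation_test <- function(signal, n_perm = 200L, seed = 1L) {
  s <- signal$amplitude
  if (stats::sd(s) == 0) return(list(statistic = 0, p_value = 1))
  lag1 <- function(x) abs(stats::cor(x[-length(x)], x[-1]))
  obs <- lag1(s)
  set.seed(as.integer(seed))
  null <- replicate(n_perm, lag1(sample(s)))
  list(statistic = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Automated reference-phase selection
#'
#' Deterministic surrogate for the visual matching of the gated
#' reconstructions to the CT: returns the phase whose gated reconstruction
#' maximizes the normalized cross-correlation between the reconstructed
#' activity and the liver mask extracted from the attenuation map (the liver
#' attenuation class), evaluated in a dilated liver neighborhood. Ties go to
#' the lowest phase index; the score is invariant to global intensity
#' scaling.
#'
#' @param recons list of gated reconstructions ([vol3d()]).
#' @param mu attenuation map ([vol3d()]).
#' @param mu_liver liver-class attenuation value in the map (default 0.0158).
#' @param dilate_vox neighborhood margin in voxels (default 4).
#' @return 0-based phase index, with per-phase scores as attribute `scores`.
#' @export
select_reference_phase <- function(recons, mu, mu_liver = 0.0158,
                                   dilate_vox = 4L) {
  if (!length(recons)) stop("select_reference_phase: no reconstructions")
  if (all(vapply(recons, function(r) sum(abs(r$data)), 0) == 0))
    stop("select_reference_phase: all reconstructions are zero")
  mask <- abs(mu$data - mu_liver) < 1e-6 * max(1, abs(mu_liver))
  if (!any(mask)) stop("select_reference_phase: no liver class in attenuation map")
  region <- dilate_mask(mask, dilate_vox)
  m <- as.numeric(mask[region])
  scores <- vapply(recons, function(r) {
    v <- r$data[region]
    if (stats::sd(v) == 0) return(-Inf)
    stats::cor(v, m)
  }, 0)
  best <- which(scores == max(scores))[1] - 1L
  structure(best, scores = scores)
}

# binary dilation by a cubic structuring element of half-width r
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- array(1, rep(2L * as.integer(r) + 1L, 3))
  conv3_cpp(array(as.numeric(mask), dim(mask)), k) > 1e-9
}
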