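test_that("DEW scatter estimate follows the window convention", {
  acq <- desk_acq()
  expect_true(all(dew_scatter_estimate(array(0, c(4, 4)), acq) == 0))
  # k = (28.1 keV / 12 keV) / 2 from the default windows
  est <- dew_scatter_estimate(1, acq)
  expect_equal(unname(est), (140.5 * 0.2) / (120 * 0.1) / 2, tolerance = 1e-12)
  expect_equal(unname(est), 1.1708, tolerance = 1e-4)
  # clipping at the observed primary counts
  expect_equal(unname(dew_scatter_estimate(10, acq, primary_counts = 3)), 3)
  acq_bad <- acq; acq_bad$scatter_width_frac <- 0
  expect_error(dew_scatter_estimate(1, acq_bad), "zero-width")
})

test_that("DEW correction moves totals toward the geometric primary truth", {
  fx <- fixture_breathing()
  ung <- ungated_projections(fx$lm)
  tp <- fx$acq$time_per_projection_s / fx$ph$n_phases
  geom_true <- (sum(fx$lm$rates$primary) - sum(fx$lm$rates$scatter)) * tp
  est <- dew_scatter_estimate(ung$scatter, fx$acq, primary_counts = ung$primary)
  err_corr <- abs(sum(ung$primary - est) - geom_true)
  err_raw <- abs(sum(ung$primary) - geom_true)
  expect_lt(err_corr, err_raw)
})

test_that("OSEM recovers a noiseless point source (matched model)", {
  n <- 16; sp <- 4.418
  mu <- vol3d(array(0.01, rep(n, 3)), spacing = rep(sp, 3))
  arr <- array(0, rep(n, 3)); arr[7, 9, 6] <- 500
  act <- vol3d(arr, spacing = rep(sp, 3))
  acq <- desk_acq(n_proj = 16L)
  angs <- projection_angles(acq)
  proj <- array(0, c(n, n, 16))
  for (a in 1:16) proj[, , a] <- forward_project(act, mu, acq, angs[a])
  rec <- osem(proj, angs, mu, acq, recon_config(1L, 150L))
  expect_lt(abs(sum(rec$data) - 500) / 500, 0.02)
  w <- rec$data / sum(rec$data)
  cen <- vapply(1:3, function(a) sum(slice.index(w, a) * w), 0)
  expect_lt(sqrt(sum((cen - c(7, 9, 6))^2)), 0.5)
  expect_true(all(rec$data >= 0))
})

test_that("all-zero projections reconstruct to the zero image", {
  n <- 12
  mu <- vol3d(array(0.01, rep(n, 3)), spacing = rep(4, 3))
  rec <- osem(array(0, c(n, n, 8)), projection_angles(desk_acq(8L)), mu,
              desk_acq(8L), recon_config(2L, 3L))
  expect_true(all(rec$data == 0))
  expect_error(osem(array(-1, c(n, n, 8)), projection_angles(desk_acq(8L)),
                    mu, desk_acq(8L)), "nonnegative")
})

test_that("MLEM log-likelihood is nondecreasing on noisy data", {
  set.seed(12)
  n <- 16; sp <- 4.418
  mu <- vol3d(array(0.012, rep(n, 3)), spacing = rep(sp, 3))
  act <- vol3d(array(0, rep(n, 3)), spacing = rep(sp, 3))
  act$data[5:11, 6:12, 5:10] <- 3
  acq <- desk_acq(n_proj = 12L)
  angs <- projection_angles(acq)
  lam <- array(0, c(n, n, 12))
  for (a in 1:12) lam[, , a] <- forward_project(act, mu, acq, angs[a])
  y <- array(rpois(length(lam), lam * 5), dim(lam))
  x <- NULL
  ll <- numeric(20)
  for (it in 1:20) {
    rec <- osem(y, angs, mu, acq, recon_config(1L, 1L), x_init = x)
    x <- rec$data
    ll[it] <- osem_loglik(rec, y, angs, mu, acq)
  }
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
})

test_that("gated reconstruction of a static phantom gives matching phases", {
  fx <- fixture_static_lm()
  recs <- reconstruct_gated_4d(fx$lm, fx$lm$events$phase_true, 8L,
                               fx$ph$phases[[1]]$mu, fx$acq,
                               recon_config(5L, 2L))
  m <- label_masks(fx$ph$phases[[1]]$labels)
  liver_means <- vapply(recs, function(r) mean(r$data[m$liver]), 0)
  expect_lt(diff(range(liver_means)) / mean(liver_means), 0.05)
  # each gated image used ~1/8 of the counts
  expect_lt(abs(sum(recs[[1]]$data) / sum(recs[[5]]$data) - 1), 0.1)
})

test_that("empty phase yields a zero image with a warning", {
  fx <- fixture_static_lm()
  labs <- fx$lm$events$phase_true
  labs[labs == 3L] <- 2L                         # empty phase 3
  expect_warning(
    recs <- reconstruct_gated_4d(fx$lm, labs, 8L, fx$ph$phases[[1]]$mu,
                                 fx$acq, recon_config(5L, 1L)),
    "no events")
  expect_true(all(recs[[4]]$data == 0))
})

test_that("2D affine registration recovers a known CC shift", {
  # two-phase phantom with a 2-voxel CC shift; noiseless expected projections
  spec <- desk_spec(amplitude_mm = c(0, 0, 2 * 4.418))
  ph <- generate_phase_set(spec, 2L)
  acq <- desk_acq(n_proj = 6L)
  rates <- mocodose:::expected_projection_rates(ph, acq)
  gated <- lapply(1:2, function(p)
    list(primary = rates$primary[, , , p], scatter = rates$scatter[, , , p]))
  tr <- register_phases_2d_affine(gated, ref = 0L, smooth_angles = 1L)
  # reference registered to itself: exact identity
  expect_equal(tr[1, , ], matrix(rep(c(1, 0, 0, 1, 0, 0), each = 6), 6),
               ignore_attr = TRUE)
  # phase 1 content sits 2 bins lower in v at every angle -> tv = -2
  expect_true(all(abs(tr[2, , 6] - (-2)) < 0.5))
  expect_true(all(abs(tr[2, , 5]) < 0.5))        # no u translation
  expect_true(all(abs(tr[2, , c(1, 4)] - 1) < 0.05))
})

test_that("3Dcomp equals 3D for a static phantom and keeps count books", {
  fx <- fixture_static_lm()
  cfgr <- recon_config(5L, 3L)
  labs <- fx$lm$events$phase_true
  gated <- bin_listmode(fx$lm, labs, 8L)
  tr <- register_phases_2d_affine(gated, ref = 0L)
  r3d <- reconstruct_3d(fx$lm, fx$ph$phases[[1]]$mu, fx$acq, cfgr)
  rcmp <- reconstruct_3dcomp(fx$lm, labs, tr, 0L, fx$ph$phases[[1]]$mu,
                             fx$acq, cfgr)
  m <- label_masks(fx$ph$phases[[1]]$labels)
  for (mask in list(m$liver, m$lungs, m$tumor_any)) {
    rel <- abs(mean(rcmp$data[mask]) - mean(r3d$data[mask])) /
      mean(r3d$data[mask])
    expect_lt(rel, 0.02)
  }
  # bookkeeping: corrected counts + clipped weight = total events, and the
  # clipped weight (boundary splats) stays a tiny fraction
  expect_equal(attr(rcmp, "corrected_counts") + attr(rcmp, "lost_weight"),
               nrow(fx$lm$events), tolerance = 1e-9)
  expect_lt(attr(rcmp, "lost_weight") / nrow(fx$lm$events), 0.005)
  expect_gte(attr(rcmp, "n_dropped"), 0)
})
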