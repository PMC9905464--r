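test_that("projector conserves mass without attenuation or PSF", {
  act <- cylinder_activity()
  mu0 <- zero_mu()
  acq <- desk_acq()
  for (ang in c(0, 47, 133, 270)) {
    p <- forward_project(act, mu0, acq, ang, use_att = FALSE, use_psf = FALSE)
    expect_lt(abs(sum(p) - sum(act$data)) / sum(act$data), 0.005)
  }
})

test_that("slab attenuation matches Beer-Lambert", {
  n <- 32; sp <- 4
  arr <- array(0, rep(n, 3)); arr[16, 8, 16] <- 100
  act <- vol3d(arr, spacing = rep(sp, 3))
  for (mu_val in c(0.01, 0.015)) for (slab_vox in c(2, 4)) {
    muarr <- array(0, rep(n, 3))
    muarr[, 17:(16 + slab_vox), ] <- mu_val
    muv <- vol3d(muarr, spacing = rep(sp, 3))
    p0 <- forward_project(act, zero_mu(n, sp), desk_acq(), 0,
                          use_att = FALSE, use_psf = FALSE)
    p1 <- forward_project(act, muv, desk_acq(), 0, use_psf = FALSE)
    expect_equal(sum(p1) / sum(p0), exp(-mu_val * slab_vox * sp),
                 tolerance = 0.005)
  }
})

test_that("point source at 100 mm projects with 7.4 mm FWHM", {
  n <- 128; sp <- 1
  acq <- acquisition_spec(det_dist_mm = 150)  # y = +50 mm -> depth 100 mm
  arr <- array(0, rep(n, 3))
  arr[64, 115, 64] <- 1000                    # (115-1) - 63.5 = 50.5 mm
  act <- vol3d(arr, spacing = rep(sp, 3))
  p <- forward_project(act, zero_mu(n, sp), acq, 0, use_att = FALSE)
  prof <- p[, 64]
  m <- sum(prof * seq_len(n)) / sum(prof)
  v <- sum(prof * (seq_len(n) - m)^2) / sum(prof)
  fwhm <- sqrt(v) * 2 * sqrt(2 * log(2)) * sp
  # model FWHM at the exact source depth (99.5 mm)
  target <- acq$psf_intercept + acq$psf_slope * 99.5
  expect_lt(abs(fwhm - target) / target, 0.02)
  expect_equal(target, 7.4, tolerance = 0.01)
})

test_that("backprojector is the exact adjoint (matrix oracle, 8^3)", {
  n <- 8
  set.seed(4)
  mu <- vol3d(array(runif(n^3, 0, 0.02), rep(n, 3)), spacing = rep(4, 3))
  acq <- desk_acq()
  for (ang in c(0, 33.3, 211)) {
    # brute-force matrix from forward-projecting basis vectors
    A <- matrix(0, n * n, n^3)
    for (j in seq_len(n^3)) {
      e <- array(0, rep(n, 3)); e[j] <- 1
      A[, j] <- as.vector(forward_project(vol3d(e, spacing = rep(4, 3)), mu,
                                          acq, ang))
    }
    y <- matrix(runif(n * n), n, n)
    bt <- back_project(y, mu, acq, ang)
    expect_equal(as.vector(t(A) %*% as.vector(y)), as.vector(bt$data),
                 tolerance = 1e-6)
    # inner-product identity
    x <- runif(n^3)
    expect_equal(sum((A %*% x) * as.vector(y)),
                 sum(x * as.vector(bt$data)), tolerance = 1e-6)
  }
})

test_that("scatter window surrogate behaves as configured", {
  act <- cylinder_activity()
  mu <- build_static_phantom(desk_spec())$mu
  acq0 <- desk_acq(scatter_fraction = 0)
  expect_true(all(simulate_scatter_window(act, mu, acq0, 30) == 0))

  acq <- desk_acq()
  geom <- forward_project(act, mu, acq, 30, use_att = FALSE, use_psf = FALSE)
  sc <- simulate_scatter_window(act, mu, acq, 30)
  expect_equal(sum(sc) / sum(geom), 0.3, tolerance = 0.02)

  # broad kernel: strictly larger spatial variance than the primary
  spat_var <- function(p) {
    w <- p / sum(p)
    mu_u <- sum(row(p) * w); mu_v <- sum(col(p) * w)
    sum(((row(p) - mu_u)^2 + (col(p) - mu_v)^2) * w)
  }
  prim <- forward_project(act, mu, acq, 30)
  expect_gt(spat_var(sc), spat_var(prim))
})

test_that("list-mode acquisition matches Poisson expectations", {
  fx <- fixture_breathing()
  lm <- fx$lm
  ev <- lm$events

  # schedule: times nondecreasing, bounded by the scan duration
  expect_true(!is.unsorted(ev$t))
  expect_lte(max(ev$t), lm$scan_time_s)
  expect_equal(lm$scan_time_s, 30 * 25)

  # total events within 3 sigma of the analytic expectation
  tp <- fx$acq$time_per_projection_s
  expected <- (sum(lm$rates$primary) + sum(lm$rates$scatter)) *
    tp / fx$ph$n_phases
  expect_lt(abs(nrow(ev) - expected), 3 * sqrt(expected))

  # event times consistent with their projection's dwell window
  expect_true(all(ev$t >= (ev$proj - 1) * tp & ev$t <= ev$proj * tp))

  # and with their true phase's (centered) intervals
  frac <- (ev$t %% fx$spec$period_s) / fx$spec$period_s
  expect_true(all(round(frac * 8) %% 8 == ev$phase_true))
})

test_that("acquisition refuses an empty phantom", {
  spec <- desk_spec(tumors = list(), conc_background = 0, conc_liver = 0,
                    lung_shunt_fraction_true = 0)
  spec$total_rate <- 0
  ph <- generate_phase_set(spec, 2L)
  expect_error(acquire_listmode(ph, desk_acq(n_proj = 2L)), "no activity")
})

test_that("gated binning partitions counts exactly", {
  fx <- fixture_breathing()
  lm <- fx$lm
  ung <- ungated_projections(lm)
  expect_equal(sum(ung$primary) + sum(ung$scatter), nrow(lm$events))

  # n_phases = 1 identity
  one <- bin_listmode(lm, rep(0L, nrow(lm$events)), 1L)[[1]]
  expect_identical(one$primary, ung$primary)

  # random assignment: counts conserved, each gate near 1/8 (multinomial 3s)
  set.seed(9)
  labs <- sample(0:7, nrow(lm$events), replace = TRUE)
  gated <- bin_listmode(lm, labs, 8L)
  tot <- Reduce(`+`, lapply(gated, function(g) g$primary + g$scatter))
  expect_identical(tot, ung$primary + ung$scatter)
  n <- nrow(lm$events)
  per <- vapply(gated, function(g) sum(g$primary) + sum(g$scatter), 0)
  expect_true(all(abs(per - n / 8) < 3 * sqrt(n * (1 / 8) * (7 / 8))))

  expect_error(bin_listmode(lm, rep(9L, n), 8L), "out of range")
})

test_that("repeated noisy projections have Poisson variance", {
  spec <- desk_spec(grid = 24L, amplitude_mm = c(0, 0, 0), tumors = list())
  ph <- generate_phase_set(spec, 1L)
  acq <- desk_acq(n_proj = 1L)
  lam <- lm_rates <- NULL
  sims <- sapply(1:60, function(i) {
    lm <- acquire_listmode(ph, acq, seed = 1000L + i)
    ung <- ungated_projections(lm)
    as.vector(ung$primary)
  })
  lam_hat <- rowMeans(sims)
  keep <- lam_hat > 20                       # stable bins only
  ratio <- apply(sims[keep, ], 1, var) / lam_hat[keep]
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})
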