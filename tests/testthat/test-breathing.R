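test_that("feature rebinning partitions events and degenerates correctly", {
  fx <- fixture_breathing()
  feat <- rebin_listmode_features(fx$lm, dt = 0.5)
  expect_equal(sum(feat$counts), nrow(fx$lm$events))
  expect_equal(nrow(feat$counts), fx$lm$scan_time_s / 0.5)

  # dt = full scan -> a single row equal to the total coarse histogram
  one <- rebin_listmode_features(fx$lm, dt = fx$lm$scan_time_s)
  expect_equal(nrow(one$counts), 1L)
  expect_equal(sum(one$counts), nrow(fx$lm$events))
  expect_equal(as.vector(one$counts), colSums(feat$counts))

  expect_error(rebin_listmode_features(fx$lm, dt = 0), "dt must be")
})

test_that("feature rows separate respiratory phases (silhouette oracle)", {
  fx <- fixture_breathing()
  feat <- rebin_listmode_features(fx$lm, dt = 0.5)
  x <- mocodose:::normalize_features(feat, 1L)
  tru <- mocodose:::phase_of_time(feat$time, fx$spec$period_s, 8L)
  g0 <- x[tru == 0L, ]; g4 <- x[tru == 4L, ]      # extreme phases
  d <- function(a, b) sqrt(sum((a - b)^2))
  within <- mean(as.matrix(dist(g0)))
  between <- mean(apply(g4, 1, function(r)
    mean(apply(g0, 1, d, b = r))))
  expect_gt(between, within)                      # silhouette > 0
})

test_that("eigenmap signal tracks the breathing waveform", {
  fx <- fixture_breathing()
  feat <- rebin_listmode_features(fx$lm, dt = 0.5)
  sig <- laplacian_eigenmap_signal(feat)
  expect_false(sig$degenerate)
  tru <- (1 - cos(2 * pi * (feat$time %% fx$spec$period_s) /
                    fx$spec$period_s)) / 2
  expect_gt(abs(cor(sig$amplitude, tru)), 0.8)
})

test_that("identical feature rows yield a degenerate flat signal", {
  feat <- structure(list(counts = matrix(5, 60, 16),
                         time = (1:60 - 0.5) * 0.5,
                         proj = rep(1L, 60),
                         cell_v = rep(1:4, each = 4),
                         coarse = c(4L, 4L), dt = 0.5, n_events = 60 * 80),
                    class = "lm_features")
  sig <- laplacian_eigenmap_signal(feat, k_neighbors = 5L)
  expect_true(sig$degenerate)
  expect_true(all(sig$amplitude == 0))
})

test_that("zero-motion signal is indistinguishable from a permutation null", {
  fx <- fixture_static_lm()
  feat <- rebin_listmode_features(fx$lm, dt = 0.5)
  sig <- laplacian_eigenmap_signal(feat)
  pt <- signal_permutation_test(sig, n_perm = 200L, seed = 3L)
  expect_gt(pt$p_value, 0.05)
})

test_that("phase assignment splits cycles into near-equal time bins", {
  fx <- fixture_breathing()
  feat <- rebin_listmode_features(fx$lm, dt = 0.5)
  sig <- laplacian_eigenmap_signal(feat)

  asg1 <- assign_phases(sig, 1L)
  expect_true(all(asg1$time_labels == 0L))

  asg <- assign_phases(sig, 8L, lm = fx$lm)
  expect_equal(asg$method, "cycles")
  # equal-time split: continuous event labels are near-uniform (time-bin
  # labels are quantized at 10 bins/cycle and cannot be)
  occ <- tabulate(asg$event_labels + 1L, 8L) / length(asg$event_labels)
  expect_true(all(abs(occ - 0.125) < 0.02))

  # every event labeled exactly once; gated counts sum to the total
  expect_equal(length(asg$event_labels), nrow(fx$lm$events))
  gated <- bin_listmode(fx$lm, asg$event_labels, 8L)
  tot <- sum(vapply(gated, function(g) sum(g$primary) + sum(g$scatter), 0))
  expect_equal(tot, nrow(fx$lm$events))
})

test_that("cycle-free signals fall back to amplitude quantiles", {
  sig <- structure(list(time = (1:100 - 0.5) * 0.5,
                        amplitude = seq(0, 1, length.out = 100),  # monotone
                        dt = 0.5, proj = rep(1L, 100)),
                   class = "resp_signal")
  expect_warning(asg <- assign_phases(sig, 4L), "quantiles")
  expect_equal(asg$method, "quantiles")
  expect_equal(sort(unique(asg$time_labels)), 0:3)
})

test_that("reference phase selection matches the attenuation phase", {
  fx <- fixture_breathing()
  # ideal gated reconstructions: the phantom's own phase activity maps
  recons <- lapply(fx$ph$phases, `[[`, "activity")
  mu3 <- fx$ph$phases[[4]]$mu
  sel <- select_reference_phase(recons, mu3,
                                mu_liver = fx$spec$attenuation$liver)
  expect_equal(as.integer(sel), 3L)

  # invariant to global intensity scaling
  recons2 <- recons
  recons2[[4]] <- vol3d(recons2[[4]]$data * 7.3, recons2[[4]]$spacing)
  expect_equal(as.integer(select_reference_phase(recons2, mu3,
                                                 mu_liver = fx$spec$attenuation$liver)), 3L)

  # zero motion: all phases tie, lowest index wins
  fs <- fixture_static_lm()
  recs <- lapply(fs$ph$phases, `[[`, "activity")
  expect_equal(as.integer(select_reference_phase(recs, fs$ph$phases[[1]]$mu,
                                                 mu_liver = fs$spec$attenuation$liver)), 0L)

  zero <- lapply(recons, function(r) vol3d(array(0, dim(r$data)), r$spacing))
  expect_error(select_reference_phase(zero, mu3), "all reconstructions are zero")
})
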