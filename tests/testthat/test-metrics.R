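test_that("comparison formulas match their definitions", {
  expect_equal(pdd(105, 100), 5)
  expect_equal(pdd(100, 100), 0)
  expect_equal(pdd(4, 8), -50)                  # patient-10 lung doses
  expect_error(pdd(1, 0), "zero 3D dose")

  expect_equal(lsf(5, 95), 5)
  expect_equal(lsf(0, 10), 0)
  expect_error(lsf(0, 0), "no counts")

  expect_equal(tn_ratio(80, 10, 200, 100), 4)
  expect_equal(tn_ratio(3, 7, 3, 7), 1)
  expect_error(tn_ratio(0, 1, 1, 1), "> 0")

  expect_equal(pda(1.57, 1.28), (1.57 - 1.28) / 1.28 * 100)
  expect_equal(pda(2, 2), 0)
  # antisymmetry vs direct recomputation with swapped arms
  set.seed(1)
  a <- runif(50, 0.5, 3); b <- runif(50, 0.5, 3)
  expect_equal(pda(a, b), -pda(b, a) * (a / b))
})

test_that("bland_altman matches brute-force limits", {
  b <- rnorm(20)
  ba <- bland_altman(b, b)
  expect_equal(ba$mean_diff, 0)
  expect_equal(unname(ba$loa), c(0, 0))

  ba1 <- bland_altman(b + 1, b)
  expect_equal(ba1$mean_diff, 1)
  expect_equal(ba1$sd_diff, 0)

  set.seed(2)
  x <- rnorm(30); y <- rnorm(30)
  ba2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(unname(ba2$loa),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
  expect_equal(ba2$pairs$mean, (x + y) / 2)
  expect_error(bland_altman(1:3, 1:4), "length mismatch")
})

test_that("amplitude estimator recovers known translations", {
  fx <- fixture_breathing()
  m <- label_masks(fx$ph$phases[[1]]$labels)
  a0 <- fx$ph$phases[[1]]$activity

  # identical images -> ~0 mm
  amp0 <- estimate_amplitude(a0, a0, m$liver)
  expect_lt(as.numeric(amp0), 0.5)

  # known quantized shift between extreme phases
  a4 <- fx$ph$phases[[5]]$activity
  truth <- sqrt(sum((fx$ph$true_translation_mm[5, ] -
                       fx$ph$true_translation_mm[1, ])^2))
  amp <- estimate_amplitude(a0, a4, m$liver)
  expect_lt(abs(as.numeric(amp) - truth), fx$spec$spacing[1] / 2)

  # tiny mask -> explicit not-estimable result
  tiny <- array(FALSE, dim(a0$data)); tiny[16, 16, 16] <- TRUE
  res <- estimate_amplitude(a0, a4, tiny)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "too small")
})

test_that("tumor features match analytic sphere geometry", {
  # 10 mm lesion centered in a 50 mm liver sphere, 2 mm voxels
  n <- 64; sp <- 2
  ctr <- rep((n / 2) * sp, 3)
  liver <- ellipsoid_vox(n, sp, ctr, 50)
  lesion <- ellipsoid_vox(n, sp, ctr, 10)
  tf <- tumor_features(lesion, liver, rep(sp, 3), cc_amplitude_mm = 9)
  f <- tf$features
  expect_equal(unname(f["volume_ml"]), 4 / 3 * pi * 10^3 / 1000,
               tolerance = 0.15)
  # lesion border to liver border: 40 mm; COM to liver border: 50 mm
  expect_lt(abs(f[["min_border_dist_mm"]] - 40), 2 * sp)
  expect_lt(abs(f[["com_border_dist_mm"]] - 50), 2 * sp)
  expect_lt(abs(f[["com_border_cc_dist_mm"]] - 50), 2 * sp)
  expect_equal(f[["cc_amplitude_mm"]], 9)
  expect_equal(tf$features_per_volume[["volume_ml"]], 1)
  expect_false(tf$outside_liver)

  # brute-force oracle for the COM-to-border distance
  border <- mocodose:::mask_border(liver)
  bidx <- which(border, arr.ind = TRUE)
  bmm <- sweep(sweep(bidx - 1, 2, rep(sp, 3), "*"), 2, rep(sp / 2, 3), "+")
  com <- colMeans(sweep(sweep(which(lesion, arr.ind = TRUE) - 1, 2,
                              rep(sp, 3), "*"), 2, rep(sp / 2, 3), "+"))
  brute <- min(sqrt(colSums((t(bmm) - com)^2)))
  expect_equal(f[["com_border_dist_mm"]], brute)
})

test_that("degenerate lesion == liver zeroes the border-distance features", {
  n <- 24; sp <- 2
  liver <- ellipsoid_vox(n, sp, rep(n, 3), 18)
  tf <- tumor_features(liver, liver, rep(sp, 3))
  f <- tf$features
  expect_equal(unname(f["min_border_dist_mm"]), 0)
  expect_equal(unname(f["mean_border_dist_mm"]), 0)
  expect_equal(unname(f["cc_gap_top_mm"]), 0)
})

test_that("stats suite branches and Spearman behave per protocol", {
  x <- rnorm(20)
  s0 <- stats_suite(x, x)
  expect_equal(s0$p_value, 1)
  expect_equal(s0$mean_diff, 0)
  expect_equal(s0$branch, "wilcoxon")           # zero differences flagged
  expect_true(length(s0$flags) > 0)

  set.seed(4)
  a <- rexp(30)^3                               # clearly non-normal
  b <- a + rnorm(30, 0, 0.1)
  expect_equal(stats_suite(a, b)$branch, "wilcoxon")

  xx <- seq(-2, 2, length.out = 25)
  sp <- stats_suite(rnorm(25), rnorm(25),
                    predictors = data.frame(f = xx), target = xx^3)
  expect_equal(sp$spearman$rho, 1)

  expect_error(stats_suite(1:2, 1:2), "n >= 3")
})

test_that("t branch is selected with calibrated power on normal pairs", {
  n <- 30; delta <- 0.5
  set.seed(6)
  res <- t(replicate(200, {
    b <- rnorm(n)
    a <- b + rnorm(n, delta, 1)
    s <- stats_suite(a, b)
    c(t_branch = s$branch == "t", reject = s$p_value < 0.05)
  }))
  expect_gte(mean(res[, "t_branch"]), 0.8)
  # closed-form noncentral-t power oracle for the paired t test
  ncp <- delta / (1 / sqrt(n))
  tc <- qt(0.975, n - 1)
  power <- 1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
  expect_lt(abs(mean(res[res[, "t_branch"] == 1, "reject"]) - power), 0.05)
})
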