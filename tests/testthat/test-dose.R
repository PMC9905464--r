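toy_vois <- function(d = c(10, 10, 10)) {
  liver <- array(FALSE, d); liver[2:5, 2:5, 2:5] <- TRUE
  lungs <- array(FALSE, d); lungs[7:9, 7:9, 7:9] <- TRUE
  derive_vois(liver, lungs, list(), pl = liver, spacing = c(4, 4, 4))
}

test_that("activity calibration is definitional and linear", {
  d <- c(10, 10, 10)
  v <- toy_vois(d)
  counts <- array(0, d)
  counts[v$liver] <- 100 / sum(v$liver)        # 100 counts in liver+lungs
  counts[1, 1, 1] <- 50                        # extrahepatic counts
  rec <- vol3d(counts, spacing = c(4, 4, 4))
  act <- calibrate_activity(rec, v, 1e9)
  expect_equal(sum(act$data[v$liver | v$lungs]), 1e9)
  expect_equal(attr(act, "calibration_factor"), 1e7)
  # extrahepatic counts scaled but excluded from normalization
  expect_gt(sum(act$data), 1e9)
  # linearity
  act2 <- calibrate_activity(rec, v, 2e9)
  expect_equal(act2$data, act$data * 2)

  expect_error(calibrate_activity(vol3d(array(0, d), spacing = 4), v, 1e9),
               "no counts")
  expect_error(calibrate_activity(rec, v, 0), "> 0")
})

test_that("local dose rate matches closed-form arithmetic", {
  d <- c(9, 9, 9)
  arr <- array(0, d); arr[5, 5, 5] <- 1e6      # 1 MBq in one voxel
  act <- vol3d(arr, spacing = c(4, 4, 4))
  r <- dose_rate(act, engine = "local")
  m_vox_kg <- (4^3 / 1000) * 1 / 1000          # 0.064 mL at 1 g/mL
  expected <- 1e6 * 0.9337 * 1.602176634e-13 / m_vox_kg
  expect_equal(r$data[5, 5, 5], expected, tolerance = 1e-12)
  expect_equal(sum(r$data > 0), 1)
  # zero activity -> zero rate
  expect_true(all(dose_rate(vol3d(array(0, d), spacing = 4))$data == 0))
})

test_that("kernel engine reaches the equilibrium (local) rate and conserves energy", {
  d <- c(17, 17, 17)
  act <- vol3d(array(1000, d), spacing = c(4.418, 4.418, 4.418))
  loc <- dose_rate(act, engine = "local")
  ker <- dose_rate(act, engine = "kernel")
  # charged-particle equilibrium at the center of a uniform region
  expect_equal(ker$data[9, 9, 9], loc$data[9, 9, 9], tolerance = 0.02)

  # energy conservation: activity far from edges, total energy rate equal
  arr <- array(0, d); arr[7:11, 7:11, 7:11] <- 500
  act2 <- vol3d(arr, spacing = c(4.418, 4.418, 4.418))
  k2 <- dose_rate(act2, engine = "kernel")
  l2 <- dose_rate(act2, engine = "local")
  expect_equal(sum(k2$data), sum(l2$data), tolerance = 0.01)
})

test_that("decay integration applies T_half/ln2 exactly", {
  d <- c(4, 4, 4)
  rate <- vol3d(array(1, d), spacing = 1)
  dm <- decay_model(64)
  dose <- integrate_decay(rate, dm)
  expect_equal(dose$data[1], 64 * 3600 / log(2), tolerance = 1e-15)
  # proportionality in half-life
  dose32 <- integrate_decay(rate, decay_model(32))
  expect_equal(dose32$data, dose$data / 2)
  expect_error(decay_model(0), "> 0")
})

test_that("mean dose equals the brute-force mask mean", {
  set.seed(8)
  d <- c(16, 16, 16)
  dose <- vol3d(array(rexp(prod(d)), d), spacing = 1)
  for (seed in 1:3) {
    set.seed(seed)
    mask <- array(runif(prod(d)) < 0.3, d)
    expect_equal(mean_dose(dose, mask), sum(dose$data[mask]) / sum(mask))
  }
  expect_error(mean_dose(dose, array(FALSE, d)), "empty VOI")
})

test_that("activity prescription is linear arithmetic", {
  expect_equal(prescribe_activity(100, 120), 1.2)
  expect_equal(prescribe_activity(100, 240), 2.4)
  expect_error(prescribe_activity(0, 120), "> 0")
  # PDA between arms is invariant to the prescription value
  d1 <- 80; d2 <- 95
  p1 <- pda(prescribe_activity(d2, 120), prescribe_activity(d1, 120))
  p2 <- pda(prescribe_activity(d2, 300), prescribe_activity(d1, 300))
  expect_equal(p1, p2)
})

test_that("DAD matches brute-force voxel reassignment", {
  d <- c(12, 12, 12)
  liver <- array(FALSE, d); liver[2:8, 2:8, 2:8] <- TRUE
  lungs <- array(FALSE, d); lungs[7:11, 7:11, 7:11] <- TRUE
  counts <- array(1, d); counts[7:8, 7:8, 7:8] <- 50  # hot overlap
  rec <- vol3d(counts, spacing = c(4, 4, 4))
  arms <- lapply(c("liver", "lungs"), function(ov) {
    v <- derive_vois(liver, lungs, list(), pl = liver & lungs | liver,
                     overlap_to = ov)
    act <- calibrate_activity(rec, v, 1e9)
    dm <- integrate_decay(dose_rate(act, "local"))
    list(v = v, dm = dm)
  })
  dd <- dad(arms[[1]]$dm, arms[[2]]$dm, arms[[1]]$v$lungs, arms[[2]]$v$lungs)
  # moving hot overlap voxels into the liver lowers the lung dose
  expect_lt(dd, 0)
  # brute-force recomputation oracle
  brute <- mean(arms[[1]]$dm$data[arms[[1]]$v$lungs]) -
    mean(arms[[2]]$dm$data[arms[[2]]$v$lungs])
  expect_equal(dd, brute)
  # identical masks (no overlap) give DAD = 0
  lungs2 <- array(FALSE, d); lungs2[10:11, 10:11, 10:11] <- TRUE
  v1 <- derive_vois(liver, lungs2, list(), liver, overlap_to = "liver")
  v2 <- derive_vois(liver, lungs2, list(), liver, overlap_to = "lungs")
  act <- calibrate_activity(rec, v1, 1e9)
  dmm <- integrate_decay(dose_rate(act, "local"))
  expect_equal(dad(dmm, dmm, v1$lungs, v2$lungs), 0)
})

test_that("packaged synthetic kernel table matches the generator", {
  csv <- read.csv(system.file("extdata", "y90_dpk_synthetic.csv",
                              package = "mocodose"))
  gen <- y90_kernel_table()
  expect_equal(nrow(csv), nrow(gen))
  expect_equal(csv$radius_mm, gen$radius_mm, tolerance = 1e-6)
  expect_equal(csv$energy_fraction_per_mm3, gen$energy_fraction_per_mm3,
               tolerance = 1e-6)
  # unit energy normalization
  shell <- 4 * pi * gen$radius_mm^2 * diff(gen$radius_mm)[1]
  expect_equal(sum(gen$energy_fraction_per_mm3 * shell), 1, tolerance = 1e-9)
})
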