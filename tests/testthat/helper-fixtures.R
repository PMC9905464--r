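# Shared fixtures. Heavy objects are built once per test run and cached.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fix)) assign(key, force(expr), .fix)
  get(key, .fix)
}

# small phantom spec for fast unit tests
desk_spec <- function(grid = 32L, rate = 4000, seed = 7L, ...) {
  phantom_spec(grid_shape = rep(grid, 3L), total_rate = rate, seed = seed, ...)
}

desk_acq <- function(n_proj = 30L, ...) {
  acquisition_spec(n_projections = n_proj, ...)
}

# moderate-count breathing scan shared by gating tests
fixture_breathing <- function() memo("breathing", {
  spec <- desk_spec()
  ph <- generate_phase_set(spec, 8L)
  acq <- desk_acq()
  lm <- acquire_listmode(ph, acq, seed = 11L)
  list(spec = spec, ph = ph, acq = acq, lm = lm)
})

# zero-attenuation map matching a grid
zero_mu <- function(grid = 32L, spacing = 4.418) {
  vol3d(array(0, rep(grid, 3L)), spacing = rep(spacing, 3L))
}

# uniform cylinder activity inside the inscribed circle (projector mass tests)
cylinder_activity <- function(grid = 32L, spacing = 4.418, seed = 1L) {
  set.seed(seed)
  arr <- array(0, rep(grid, 3L))
  cx <- (grid + 1) / 2
  r2 <- (grid / 3)^2
  for (i in seq_len(grid)) for (j in seq_len(grid))
    if ((i - cx)^2 + (j - cx)^2 < r2)
      arr[i, j, (grid %/% 4):(3 * grid %/% 4)] <- stats::runif(1 + grid %/% 2)
  vol3d(arr, spacing = rep(spacing, 3L))
}

# zero-motion scan shared by null-signal tests
fixture_static_lm <- function() memo("static_lm", {
  spec <- desk_spec(grid = 24L, rate = 3000, amplitude_mm = c(0, 0, 0))
  ph <- generate_phase_set(spec, 8L)
  acq <- desk_acq(n_proj = 10L)
  list(spec = spec, ph = ph, acq = acq,
       lm = acquire_listmode(ph, acq, seed = 21L))
})

# voxelized sphere/ellipsoid mask on an n^3 grid (mm geometry, voxel centers)
ellipsoid_vox <- function(n, spacing, center_mm, radius_mm) {
  ax <- ((seq_len(n) - 0.5) * spacing)
  r <- if (length(radius_mm) == 1L) rep(radius_mm, 3L) else radius_mm
  dx2 <- ((ax - center_mm[1]) / r[1])^2
  dy2 <- ((ax - center_mm[2]) / r[2])^2
  dz2 <- ((ax - center_mm[3]) / r[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# best phase-label agreement over cyclic shifts
cyclic_accuracy <- function(labels, truth, n_phases) {
  max(vapply(seq_len(n_phases) - 1L, function(s)
    mean((labels + s) %% n_phases == truth), 0))
}
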