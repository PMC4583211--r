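test_that("noiseless moment recovery is exact for the mono scenario", {
  g <- orientation_grid(20, 40)
  ds <- synth_mono_vtvh(sigma_rel = 0, seed = 1, grid = g)
  fit <- fit_transition_moments(ds[[1]], mono_system(), grid = g)
  # generated with products (0, 1, 1): a purely z-polarized band
  expect_equal(unname(fit$polarizations[[1]]), c(0, 0, 100),
               tolerance = 0.5)
  expect_false(fit$degenerate[1])
  # the fitted moments reproduce the data to numerical precision
  expect_lt(fit$sse, 1e-16)
})

test_that("all-zero data yields zero products flagged degenerate", {
  d <- vtvh_dataset(700, B = rep(c(1, 3, 5, 7), 2),
                    T = rep(c(2, 10), each = 4),
                    intensity = rep(0, 8))
  fit <- fit_transition_moments(d, mono_system(), grid = coarse_grid())
  expect_true(fit$degenerate[1])
  m <- fit$moments[[1]]
  expect_equal(c(m$M_xy, m$M_xz, m$M_yz), c(0, 0, 0))
})

test_that("moment fits are invariant under point reordering", {
  g <- coarse_grid()
  ds <- synth_mono_vtvh(sigma_rel = 0.02, seed = 5, grid = g)[[2]]
  perm <- rev(seq_len(nrow(ds)))
  ds_perm <- vtvh_dataset(attr(ds, "wavelength_nm"), ds$B_T[perm],
                          ds$T_K[perm], ds$intensity[perm], ds$sigma[perm])
  f1 <- fit_transition_moments(ds, mono_system(), grid = g)
  f2 <- fit_transition_moments(ds_perm, mono_system(), grid = g)
  expect_equal(f1$moments[[1]], f2$moments[[1]], tolerance = 1e-9)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-9)
})

test_that("sign gauge fixes M_xz >= 0 without changing predictions", {
  g <- coarse_grid()
  sys <- mono_system()
  m_true <- transition_moments(0.5, -1, 0.8)
  pts <- expand.grid(B = c(2, 5, 8), T = c(2, 5, 20))
  I <- powder_cterm_intensity(sys, m_true, pts$B, pts$T, grid = g)
  d <- vtvh_dataset(600, pts$B, pts$T, I)
  fit <- fit_transition_moments(d, sys, grid = g)
  m <- fit$moments[[1]]
  expect_gte(m$M_xz, 0)
  I_fit <- powder_cterm_intensity(sys, m, pts$B, pts$T, grid = g)
  expect_equal(I_fit, I, tolerance = 1e-8)
})

test_that("noise-free SH fit started at truth is a fixed point", {
  g <- coarse_grid()
  ds <- synth_mono_vtvh(sigma_rel = 0, seed = 1, grid = g)
  spec <- fit_spec(free = "D_1", lower = c(D_1 = 1), upper = c(D_1 = 60),
                   n_starts = 1, seed = 1)
  fit <- fit_spin_hamiltonian(ds, mono_system(), spec, grid = g)
  expect_equal(unname(fit$parameters["D_1"]), 28, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-12)
})

test_that("mono D recovery bias vanishes as noise decreases", {
  g <- coarse_grid()
  spec <- fit_spec(free = "D_1", lower = c(D_1 = 1), upper = c(D_1 = 60),
                   n_starts = 2, seed = 2)
  start <- mono_system(D = 12)
  errs <- vapply(c(0, 0.005, 0.01), function(s) {
    ds <- synth_mono_vtvh(sigma_rel = s, seed = 7, grid = g)
    fit <- fit_spin_hamiltonian(ds, start, spec, grid = g)
    abs(unname(fit$parameters["D_1"]) - 28)
  }, numeric(1))
  expect_lt(errs[1], 1e-2)
  expect_lt(errs[2], 1.5)
  expect_lt(errs[3], 3)
})

test_that("fits are bit-for-bit reproducible given seed and data", {
  g <- coarse_grid()
  ds <- synth_mono_vtvh(sigma_rel = 0.01, seed = 3, grid = g)
  spec <- fit_spec(free = "D_1", lower = c(D_1 = 1), upper = c(D_1 = 60),
                   n_starts = 3, seed = 9)
  f1 <- fit_spin_hamiltonian(ds, mono_system(D = 20), spec, grid = g)
  f2 <- fit_spin_hamiltonian(ds, mono_system(D = 20), spec, grid = g)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$restarts, f2$restarts)
})

test_that("releasing a constraint never increases the optimal SSE", {
  g <- coarse_grid()
  dd <- synth_dimer_vtvh(fields = c(1, 3, 5, 7), sigma_rel = 0.01, seed = 4,
                         grid = g)
  start <- dimer_system()
  start$sites[[2]]$zfs$D <- 10
  spec1 <- fit_spec(free = "D_2", lower = c(D_2 = 0.5), upper = c(D_2 = 40),
                    n_starts = 2, seed = 1)
  spec2 <- fit_spec(free = c("D_2", "EoD_2"), lower = c(D_2 = 0.5),
                    upper = c(D_2 = 40), n_starts = 2, seed = 1)
  f1 <- fit_spin_hamiltonian(dd, start, spec1, grid = g)
  f2 <- fit_spin_hamiltonian(dd, start, spec2, grid = g)
  expect_lte(f2$sse, f1$sse * (1 + 1e-6))
})

test_that("under-determined specifications are flagged, not silent", {
  g <- coarse_grid()
  d <- synth_mono_vtvh(temps = c(2, 5), sigma_rel = 0.01, seed = 1,
                       grid = g)[[1]]   # 2 points vs 4 parameters
  spec <- fit_spec(free = "D_1", lower = c(D_1 = 1), upper = c(D_1 = 60),
                   n_starts = 1, seed = 1)
  expect_warning(fit <- fit_spin_hamiltonian(list(d), mono_system(), spec,
                                             grid = g),
                 "under-determined")
  expect_true(fit$underdetermined)
})

test_that("error-surface scan reproduces the unconstrained optimum", {
  g <- coarse_grid()
  ds <- synth_mono_vtvh(sigma_rel = 0.01, seed = 6, grid = g)
  spec <- fit_spec(free = "D_1", lower = c(D_1 = 1), upper = c(D_1 = 60),
                   n_starts = 2, seed = 2)
  fit <- fit_spin_hamiltonian(ds, mono_system(D = 15), spec, grid = g)
  scan <- scan_error_surface(ds, mono_system(D = 15), spec, "D_1",
                             unname(fit$parameters["D_1"]), grid = g)
  expect_equal(scan$sse[1], fit$sse, tolerance = 1e-6)
  expect_error(scan_error_surface(ds, mono_system(), spec, "D_1", 500,
                                  grid = g), "bounds")
})

test_that("fit_spec validates its inputs", {
  expect_error(fit_spec(free = "banana"), "unknown")
  expect_error(fit_spec(free = "D_1", lower = c(D_1 = -Inf)), "finite")
  expect_error(fit_spec(free = "J", lower = c(J = 50), upper = c(J = 10)),
               "below")
  s <- fit_spec(free = "EoD_2", upper = c(EoD_2 = 2))
  expect_lte(s$upper["EoD_2"], 1 / 3)
})
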