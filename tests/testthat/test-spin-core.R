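test_that("spin matrices obey the angular-momentum algebra", {
  for (S in c(1 / 2, 1, 3 / 2, 2, 5 / 2)) {
    m <- spin_matrices(S)
    n <- 2 * S + 1
    # [Sx, Sy] = i Sz and the Casimir S^2 = S(S+1) I
    comm <- m$x %*% m$y - m$y %*% m$x
    expect_lt(max(Mod(comm - 1i * m$z)), 1e-12)
    S2 <- m$x %*% m$x + m$y %*% m$y + m$z %*% m$z
    expect_lt(max(Mod(S2 - S * (S + 1) * diag(n))), 1e-12)
    expect_lt(max(Mod(m$x - Conj(t(m$x)))), 1e-12)
  }
  expect_equal(Re(diag(spin_matrices(1)$z)), c(1, 0, -1))
  # S = 1/2: half the Pauli matrices
  m <- spin_matrices(1 / 2)
  expect_equal(m$x, matrix(c(0, 0.5, 0.5, 0), 2) + 0i)
  expect_equal(m$z, diag(c(0.5, -0.5)) + 0i)
  expect_error(spin_matrices(0.7), "half-integer")
})

test_that("ZFS tensor has the correct principal form and rotates rigidly", {
  Dt <- zfs_tensor(zfs_params(D = 28, E_over_D = 0))
  expect_equal(Dt, diag(c(-28 / 3, -28 / 3, 56 / 3)), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:10) {
    z <- zfs_params(D = runif(1, -30, 30), E_over_D = runif(1, 0, 1 / 3),
                    euler = runif(3, -180, 180))
    Dt <- zfs_tensor(z)
    expect_lt(abs(sum(diag(Dt))), 1e-12)
    expect_lt(max(abs(Dt - t(Dt))), 1e-12)
    E <- z$E_over_D * z$D
    ref <- sort(c(-z$D / 3 + E, -z$D / 3 - E, 2 * z$D / 3))
    expect_equal(sort(eigen(Dt, symmetric = TRUE)$values), ref,
                 tolerance = 1e-10)
  }

  # a 90-degree rotation about the frame X axis, expressed in Z-Y-Z angles
  # as (-90, 90, 90): principal values preserved, axes permuted
  z0 <- zfs_params(D = 5.3, E_over_D = 0.30)
  zr <- zfs_params(D = 5.3, E_over_D = 0.30, euler = c(-90, 90, 90))
  ev0 <- sort(eigen(zfs_tensor(z0))$values)
  evr <- sort(eigen(zfs_tensor(zr))$values)
  expect_equal(evr, ev0, tolerance = 1e-10)
  Rx <- oracle_rot(-90, 90, 90)
  expect_equal(Rx %*% c(0, 1, 0), matrix(c(0, 0, 1)), tolerance = 1e-12)
})

test_that("single-site Hamiltonian reproduces textbook limits", {
  # zero-field gap D between Ms = +/-1 and Ms = 0 for S = 1
  H <- build_hamiltonian(mono_system())
  e <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(e[2] - e[1], 28, tolerance = 1e-10)
  expect_equal(e[3], e[2], tolerance = 1e-10)

  # pure Zeeman: equally spaced levels g*beta*B
  sysz <- spin_system(spin_site(1, zfs_params(0), g = 2))
  e <- sort(eigen(build_hamiltonian(sysz, field_vector(10)),
                  symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(diff(e), rep(2 * BETA * 10, 2), tolerance = 1e-10)
})

test_that("dimer Hamiltonian matches the brute-force Kronecker oracle", {
  # exchange-only multiplets at -J[S(S+1) - 4] with degeneracies 5, 3, 1
  d0 <- spin_system(list(spin_site(1, zfs_params(0)),
                         spin_site(1, zfs_params(0))),
                    exchange = exchange_coupling(35, "minus2J"))
  e <- sort(eigen(build_hamiltonian(d0), symmetric = TRUE,
                  only.values = TRUE)$values)
  expect_equal(e, c(rep(-70, 5), rep(70, 3), 140), tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    D1 <- runif(1, -30, 30); E1 <- runif(1, 0, 1 / 3)
    D2 <- runif(1, -30, 30); E2 <- runif(1, 0, 1 / 3)
    eu1 <- runif(3, -180, 180); eu2 <- runif(3, -180, 180)
    J <- runif(1, -50, 50); B <- runif(1, 0, 10)
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    g1 <- runif(1, 1.9, 2.3); g2 <- runif(1, 1.9, 2.3)
    sys <- spin_system(
      list(spin_site(1, zfs_params(D1, E1, eu1), g = g1),
           spin_site(1, zfs_params(D2, E2, eu2), g = g2)),
      exchange = exchange_coupling(J, "minus2J"))
    H <- build_hamiltonian(sys, field_vector(B, th, ph))
    l <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    Href <- oracle_dimer_H(1, 1, D1, E1, eu1, D2, E2, eu2, g1, g2, J, B, l)
    expect_lt(max(Mod(H - Href)), 1e-9)
    expect_lt(max(Mod(H - Conj(t(H)))), 1e-12)
    expect_true(all(abs(Im(eigen(H)$values)) < 1e-9))
  }
})

test_that("exchange convention conversion preserves the spectrum", {
  cpl <- exchange_coupling(35, "minus2J")
  conv <- convert_exchange_convention(cpl, "plusJ")
  expect_equal(conv$J, -70)
  back <- convert_exchange_convention(conv, "minus2J")
  expect_equal(back$J, 35)

  mk <- function(exch) {
    spin_system(list(spin_site(1, zfs_params(28)),
                     spin_site(1, zfs_params(5.3, 0.3, c(0, 90, 0)))),
                exchange = exch)
  }
  e1 <- sort(eigen(build_hamiltonian(mk(cpl), field_vector(5, 1, 2)),
                   symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sort(eigen(build_hamiltonian(mk(conv), field_vector(5, 1, 2)),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("thermal sublevels give Boltzmann populations and spin moments", {
  sys <- mono_system()
  # Ms = -1 eigenstate at 10 T along z: <Sx> = <Sy> = 0, <Sz> = -1
  sl <- thermal_sublevels(sys, field_vector(10), T = 20)
  expect_equal(sum(sl$populations), 1, tolerance = 1e-12)
  i_m1 <- which.min(abs(sl$spin_expectations[, "z"] + 1))
  expect_equal(unname(sl$spin_expectations[i_m1, ]), c(0, 0, -1),
               tolerance = 1e-6)
  expect_true(all(abs(sl$spin_expectations) <= 1 + 1e-9))

  # T -> infinity: uniform populations
  sl_hot <- thermal_sublevels(sys, field_vector(10), T = 1e7)
  expect_equal(sl_hot$populations, rep(1 / 3, 3), tolerance = 1e-4)

  # B = 0, T = 2 K: Ms = 0 population essentially 1 (gap 28 vs kT 1.39)
  sl0 <- thermal_sublevels(sys, field_vector(0), T = 2)
  expect_gt(sl0$populations[1], 0.999)

  # time reversal at B = 0: thermally weighted <s_u> vanishes
  for (sys_i in list(sys, dimer_system())) {
    sl <- thermal_sublevels(sys_i, field_vector(0), T = 5)
    mags <- colSums(sl$populations * sl$spin_expectations)
    expect_lt(max(abs(mags)), 1e-9)
  }

  expect_error(thermal_sublevels(sys, field_vector(1), T = 0), "> 0")
  expect_error(thermal_sublevels(sys, field_vector(1), T = 5,
                                 mode = "site-A"), "two-site")
})

test_that("strong exchange projects onto an effective S = 2 multiplet", {
  J <- 2000
  sys <- spin_system(
    list(spin_site(1, zfs_params(28, 0), g = 2),
         spin_site(1, zfs_params(5.3, 0.30, c(0, 90, 0)), g = 2)),
    exchange = exchange_coupling(J, "minus2J"))
  e_full <- sort(eigen(build_hamiltonian(sys), symmetric = TRUE,
                       only.values = TRUE)$values)[1:5]

  # oracle: numerically project the ZFS part onto the lowest multiplet of
  # the exchange-only Hamiltonian and diagonalize the 5x5 block
  H_ex <- oracle_dimer_H(1, 1, 0, 0, c(0, 0, 0), 0, 0, c(0, 0, 0),
                         2, 2, J, 0, c(0, 0, 1))
  H_all <- oracle_dimer_H(1, 1, 28, 0, c(0, 0, 0), 5.3, 0.30, c(0, 90, 0),
                          2, 2, J, 0, c(0, 0, 1))
  ed <- eigen(H_ex, symmetric = TRUE)
  P <- ed$vectors[, order(Re(ed$values))[1:5]]
  block <- Conj(t(P)) %*% (H_all - H_ex) %*% P
  e_proj <- sort(Re(eigen(block, symmetric = TRUE, only.values = TRUE)$values))
  e_proj <- e_proj - 2 * J   # exchange energy -2J of the S = 2 multiplet
  expect_equal(e_full, e_proj, tolerance = 0.3)
})

test_that("spin systems serialize losslessly to YAML and JSON", {
  sys <- dimer_system()
  lst <- spin_system_to_list(sys)
  expect_identical(spin_system_from_list(lst), sys)

  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_spin_system(sys, path)
    back <- read_spin_system(path)
    expect_equal(back, sys, tolerance = 1e-12)
    unlink(path)
  }
  expect_error(spin_system_from_list(list(sites = list(list(S = 1)),
                                          bogus = 1)), "unknown keys")
})

test_that("invalid spin system inputs are rejected", {
  expect_error(zfs_params(D = 28, E_over_D = 0.5), "1/3")
  expect_error(spin_site(1, zfs_params(28), g = c(-2, 2, 2)))
  expect_error(spin_system(list(spin_site(1), spin_site(1))), "exchange")
  expect_error(spin_system(spin_site(1),
                           exchange = exchange_coupling(10)), "single-site")
  expect_error(field_vector(-1), "non-negative")
})
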