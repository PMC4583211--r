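orbs <- c("d_xy", "d_xz", "d_yz", "d_z2", "d_x2-y2")

test_that("d-orbital angular momentum matches the symbolic oracle table", {
  tab <- oracle_angmom_table()
  for (u in c("x", "y", "z")) {
    for (a in orbs) {
      for (b in orbs) {
        expect_equal(d_orbital_angmom(a, b, u), tab[[u]][a, b],
                     tolerance = 1e-12,
                     label = sprintf("<%s|l_%s|%s>", a, u, b))
      }
    }
  }
})

test_that("l matrix elements are antisymmetric with zero diagonal", {
  for (u in c("x", "y", "z")) {
    for (a in orbs) {
      expect_identical(d_orbital_angmom(a, a, u), 0)
      for (b in orbs) {
        expect_equal(d_orbital_angmom(a, b, u),
                     -d_orbital_angmom(b, a, u), tolerance = 1e-12)
      }
    }
  }
})

test_that("the in-plane E pair gives a negative lower C-term and positive pseudo-A", {
  pr <- complex1_pairs()$E_x2y2
  expect_identical(cterm_sign_saturation(pr, "lower"), -1L)
  expect_identical(cterm_sign_saturation(pr, "upper"), 1L)
  expect_identical(pseudo_a_sign(pr), 1L)
})

test_that("the E pair reaching d_z2 gives a negative pseudo-A", {
  expect_identical(pseudo_a_sign(complex1_pairs()$E_z2), -1L)
})

test_that("the two C-terms of any coupled pair have opposite signs", {
  dip <- list(`+x` = "+x", `-x` = "-x", `+y` = "+y", `-y` = "-y",
              `+z` = "+z", `-z` = "-z")
  count <- 0L
  for (edo1 in orbs) for (edo2 in orbs) {
    if (edo1 == edo2) next
    for (eao in orbs) {
      if (eao %in% c(edo1, edo2)) next
      for (d1 in dip) for (d2 in dip) {
        t1 <- one_electron_transition(edo1, eao, d1, 10000)
        t2 <- one_electron_transition(edo2, eao, d2, 12000)
        pr <- excited_state_pair(t1, t2)
        s_low <- tryCatch(cterm_sign_saturation(pr, "lower"),
                          error = function(e) NULL)
        if (is.null(s_low)) next
        expect_identical(cterm_sign_saturation(pr, "upper"), -s_low)
        count <- count + 1L
      }
    }
  }
  expect_gt(count, 50)   # many geometrically valid pairs exercised
})

test_that("pseudo-A sign is independent of the order of the constituents", {
  t_low <- one_electron_transition("d_xz", "d_x2-y2", "-x", 13700)
  t_high <- one_electron_transition("d_yz", "d_x2-y2", "-y", 15220)
  s1 <- pseudo_a_sign(excited_state_pair(t_low, t_high))
  # exchange which member lies lower in energy
  t_low2 <- one_electron_transition("d_xz", "d_x2-y2", "-x", 15220)
  t_high2 <- one_electron_transition("d_yz", "d_x2-y2", "-y", 13700)
  s2 <- pseudo_a_sign(excited_state_pair(t_low2, t_high2))
  expect_identical(s1, s2)
  # and of the argument order
  expect_identical(pseudo_a_sign(excited_state_pair(t_high, t_low)), s1)
})

test_that("flipping both dipoles preserves the sign, flipping one inverts it", {
  mk <- function(d1, d2) {
    excited_state_pair(
      one_electron_transition("d_xz", "d_x2-y2", d1, 13700),
      one_electron_transition("d_yz", "d_x2-y2", d2, 15220))
  }
  base <- pseudo_a_sign(mk("-x", "-y"))
  expect_identical(pseudo_a_sign(mk("+x", "+y")), base)
  expect_identical(pseudo_a_sign(mk("+x", "-y")), -base)
  expect_identical(pseudo_a_sign(mk("-x", "+y")), -base)
})

test_that("algebraic rule agrees with the geometric handedness rule", {
  # geometric rule: with Delta_KJ > 0, a left-handed (negative determinant)
  # triple (D_J, D_K, L) absorbs right-circular light: negative C-term
  tab <- oracle_angmom_table()
  axes <- list(`+x` = c(1, 0, 0), `-x` = c(-1, 0, 0),
               `+y` = c(0, 1, 0), `-y` = c(0, -1, 0),
               `+z` = c(0, 0, 1), `-z` = c(0, 0, -1))
  count <- 0L
  for (edo1 in orbs) for (edo2 in orbs) {
    if (edo1 == edo2) next
    for (eao in setdiff(orbs, c(edo1, edo2))) {
      L <- vapply(c("x", "y", "z"),
                  function(u) tab[[u]][edo1, edo2], numeric(1))
      for (n1 in names(axes)) for (n2 in names(axes)) {
        D1 <- axes[[n1]]; D2 <- axes[[n2]]
        det3 <- det(rbind(D1, D2, L))
        if (abs(det3) < 1e-9) next
        pr <- excited_state_pair(
          one_electron_transition(edo1, eao, n1, 10000),
          one_electron_transition(edo2, eao, n2, 12000))
        expect_identical(cterm_sign_saturation(pr, "lower"),
                         as.integer(sign(det3)))
        count <- count + 1L
      }
    }
  }
  expect_gt(count, 50)
})

test_that("degenerate sign-rule inputs raise errors", {
  expect_error(one_electron_transition("d_xz", "d_xz", "-x", 100), "differ")
  t1 <- one_electron_transition("d_xz", "d_x2-y2", "-x", 13700)
  expect_error(excited_state_pair(
    t1, one_electron_transition("d_yz", "d_x2-y2", "-y", 13700)),
    "distinct energies")
  # parallel dipoles
  pr <- excited_state_pair(
    t1, one_electron_transition("d_yz", "d_x2-y2", "+x", 15220))
  expect_error(cterm_sign_saturation(pr), "parallel")
  # no shared orbital
  pr2 <- excited_state_pair(
    one_electron_transition("d_xz", "d_z2", "-x", 10000),
    one_electron_transition("d_yz", "d_x2-y2", "-y", 12000))
  expect_error(cterm_sign_saturation(pr2), "common orbital")
  # coupling vector orthogonal to the dipole-plane normal
  pr3 <- excited_state_pair(
    one_electron_transition("d_xz", "d_x2-y2", "-x", 10000),
    one_electron_transition("d_yz", "d_x2-y2", "+z", 12000))
  expect_error(cterm_sign_saturation(pr3), "component")
})
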