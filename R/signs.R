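# MCD C-term and pseudo-A-term sign prediction for one-electron d-d
# transitions, from one-electron orbital angular-momentum matrix elements
# between real d orbitals, the transition-dipole directions, and the energy
# ordering of the two spin-orbit-coupled excited states.

.D_ORBITALS <- c("d_xy", "d_xz", "d_yz", "d_z2", "d_x2-y2")

# real d orbitals expanded in the complex |l=2, m> basis (m = 2, 1, 0, -1, -2,
# Condon-Shortley phases):
#   d_z2    = |0>
#   d_xz    = (|-1> - |+1>)/sqrt(2)
#   d_yz    = i(|-1> + |+1>)/sqrt(2)
#   d_x2-y2 = (|+2> + |-2>)/sqrt(2)
#   d_xy    = -i(|+2> - |-2>)/sqrt(2)
.d_orbital_coefficients <- function() {
  s2 <- 1 / sqrt(2)
  C <- matrix(0 + 0i, nrow = 5, ncol = 5,
              dimnames = list(.D_ORBITALS, c("2", "1", "0", "-1", "-2")))
  C["d_z2", "0"] <- 1
  C["d_xz", "1"] <- -s2; C["d_xz", "-1"] <- s2
  C["d_yz", "1"] <- 1i * s2; C["d_yz", "-1"] <- 1i * s2
  C["d_x2-y2", "2"] <- s2; C["d_x2-y2", "-2"] <- s2
  C["d_xy", "2"] <- -1i * s2; C["d_xy", "-2"] <- 1i * s2
  C
}

#' One-electron orbital angular momentum between real d orbitals
#'
#' Matrix elements <orb1 | l_u | orb2> of the one-electron orbital
#' angular-momentum operator (units of hbar) between real d orbitals. These
#' elements are purely imaginary; the signed imaginary part is returned
#' (i.e. the element is `1i * value`). Antisymmetric under exchange of the
#' two orbitals, and zero on the diagonal: real orbitals carry no net
#' angular momentum.
#'
#' @param orb1,orb2 orbital labels from
#'   `c("d_xy", "d_xz", "d_yz", "d_z2", "d_x2-y2")`
#' @param component `"x"`, `"y"` or `"z"`
#' @return Signed imaginary part, a single number in units of hbar.
#' @examples
#' d_orbital_angmom("d_yz", "d_xz", "z")      # +1
#' d_orbital_angmom("d_x2-y2", "d_xy", "z")   # -2
#' @export
d_orbital_angmom <- function(orb1, orb2, component = c("x", "y", "z")) {
  component <- match.arg(component)
  orb1 <- match.arg(orb1, .D_ORBITALS)
  orb2 <- match.arg(orb2, .D_ORBITALS)
  L <- spin_matrices(2)[[component]]   # same ladder algebra, l = 2
  C <- .d_orbital_coefficients()
  el <- sum(Conj(C[orb1, ]) * (L %*% C[orb2, ]))
  if (abs(Re(el)) > 1e-12) {
    stop("internal error: real part of an l matrix element", call. = FALSE)
  }
  Im(el)
}

.parse_dipole <- function(dipole) {
  if (is.character(dipole)) {
    m <- regmatches(dipole, regexec("^([+-]?)([xyz])$", dipole))[[1]]
    if (length(m) != 3L) {
      stop("dipole must be like '-x', '+y', 'z', or a length-3 vector",
           call. = FALSE)
    }
    sgn <- if (identical(m[2], "-")) -1 else 1
    v <- c(x = 0, y = 0, z = 0)
    v[m[3]] <- sgn
    unname(v)
  } else {
    stopifnot(is.numeric(dipole), length(dipole) == 3L)
    nrm <- sqrt(sum(dipole^2))
    if (nrm == 0) stop("zero dipole direction", call. = FALSE)
    dipole / nrm
  }
}

#' A one-electron d-d transition
#'
#' @param edo electron-donating orbital label
#' @param eao electron-accepting orbital label (must differ from `edo`)
#' @param dipole transition-dipole direction: `"+x"`, `"-y"`, ... or a
#'   numeric length-3 vector (normalized internally)
#' @param energy transition energy, cm^-1 (only the ordering within a pair
#'   matters)
#' @return An object of class `one_electron_transition`.
#' @examples
#' one_electron_transition("d_xz", "d_x2-y2", "-x", 13700)
#' @export
one_electron_transition <- function(edo, eao, dipole, energy) {
  edo <- match.arg(edo, .D_ORBITALS)
  eao <- match.arg(eao, .D_ORBITALS)
  if (identical(edo, eao)) {
    stop("donating and accepting orbitals must differ", call. = FALSE)
  }
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
  structure(list(edo = edo, eao = eao, dipole = .parse_dipole(dipole),
                 energy = energy),
            class = "one_electron_transition")
}

#' A pair of spin-orbit-coupled excited states
#'
#' Two one-electron transitions sharing a common orbital (a common acceptor,
#' as in the two components of an E state reached from d_xz/d_yz, or a
#' common donor). Their spin-orbit coupling generates a derivative-shaped
#' pseudo-A feature: two C-terms of opposite sign.
#'
#' @param t1,t2 [one_electron_transition()] objects with distinct energies
#' @return An object of class `excited_state_pair` with the pair stored in
#'   ascending energy order.
#' @export
excited_state_pair <- function(t1, t2) {
  stopifnot(inherits(t1, "one_electron_transition"),
            inherits(t2, "one_electron_transition"))
  if (t1$energy == t2$energy) {
    stop("the two transitions must have distinct energies", call. = FALSE)
  }
  if (t1$energy > t2$energy) { tmp <- t1; t1 <- t2; t2 <- tmp }
  structure(list(lower = t1, upper = t2,
                 delta = t2$energy - t1$energy),
            class = "excited_state_pair")
}

# reduced one-electron SOC coupling vector between the two states of a pair,
# evaluated in the J, K convention (J = the transition whose sign is sought,
# K = its partner):
#   shared acceptor: states differ in the donor hole  -> <edo_J | l | edo_K>
#   shared donor:    states differ in the excited e-  -> <eao_K | l | eao_J>
# Both choices are antisymmetric under J <-> K, which enforces the opposite
# signs of the two C-terms of a pair.
.soc_vector <- function(trans_J, trans_K) {
  if (identical(trans_J$eao, trans_K$eao)) {
    o1 <- trans_J$edo; o2 <- trans_K$edo
  } else if (identical(trans_J$edo, trans_K$edo)) {
    o1 <- trans_K$eao; o2 <- trans_J$eao
  } else {
    stop("the two transitions share no common orbital; the one-electron ",
         "spin-orbit coupling between them vanishes", call. = FALSE)
  }
  vapply(c("x", "y", "z"), function(u) d_orbital_angmom(o1, o2, u),
         numeric(1))
}

#' MCD C-term sign of one member of a coupled pair, saturation limit
#'
#' In the low-temperature saturation limit the C-term sign of a transition J
#' that borrows its MCD intensity from spin-orbit coupling to a partner
#' state K is determined by the energy denominator, the one-electron
#' angular-momentum coupling L^KJ between the two states, and the vector
#' product of the two transition dipoles:
#' sign = sign( sum_t L_t^KJ (D^J x D^K)_t / Delta_KJ ),
#' Delta_KJ = E_K - E_J. Equivalently (graphical rule): if the two dipoles
#' and the reduced spin-orbit vector form a left-handed system, the lower
#' energy transition absorbs right-circularly polarized light and its
#' C-term is negative. The two members of a pair always return opposite
#' signs.
#'
#' All signs are stated under the Condon-Shortley-derived real d-orbital
#' phase convention documented in [d_orbital_angmom()].
#'
#' @param pair an [excited_state_pair()]
#' @param which `"lower"` or `"upper"`: which member's sign to return
#' @return +1 or -1.
#' @examples
#' # the E(d_xz,yz -> d_x2-y2) pair: lower component negative
#' pr <- excited_state_pair(
#'   one_electron_transition("d_xz", "d_x2-y2", "-x", 13700),
#'   one_electron_transition("d_yz", "d_x2-y2", "-y", 15220))
#' cterm_sign_saturation(pr, "lower")   # -1
#' cterm_sign_saturation(pr, "upper")   # +1
#' @export
cterm_sign_saturation <- function(pair, which = c("lower", "upper")) {
  stopifnot(inherits(pair, "excited_state_pair"))
  which <- match.arg(which)
  tJ <- pair[[which]]
  tK <- if (which == "lower") pair$upper else pair$lower
  delta <- tK$energy - tJ$energy
  L <- .soc_vector(tJ, tK)
  cr <- cross3(tJ$dipole, tK$dipole)
  if (sum(cr^2) < 1e-12) {
    stop("transition dipoles are parallel; the pair carries no C-term ",
         "intensity in this model", call. = FALSE)
  }
  s <- sum(L * cr)
  if (abs(s) < 1e-12) {
    stop("no spin-orbit coupling component along the dipole-plane normal",
         call. = FALSE)
  }
  as.integer(sign(s / delta))
}

#' Pseudo-A-term sign of a coupled pair
#'
#' The sign of a pseudo-A feature is defined as the sign of its
#' higher-energy C-term component. It is independent of which member of the
#' pair happens to lie lower in energy, and is unchanged when both dipole
#' directions are flipped (the rule is bilinear in the dipoles).
#'
#' @param pair an [excited_state_pair()]
#' @return +1 or -1.
#' @examples
#' pr <- excited_state_pair(
#'   one_electron_transition("d_xz", "d_x2-y2", "-x", 13700),
#'   one_electron_transition("d_yz", "d_x2-y2", "-y", 15220))
#' pseudo_a_sign(pr)   # +1
#' @export
pseudo_a_sign <- function(pair) {
  cterm_sign_saturation(pair, "upper")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
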