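# Independent oracles, coded without reference to the package internals.

BETA <- 0.4668645   # cm^-1 / T
KB <- 0.6950348     # cm^-1 / K

# --- brute-force spin Hamiltonian ------------------------------------------
# Spin matrices via explicit ladder algebra (independent of the package's
# constructor: different loop structure and basis bookkeeping).
oracle_spin_mats <- function(S) {
  n <- round(2 * S + 1)
  m_vals <- S - (0:(n - 1))          # S, S-1, ..., -S
  Sz <- diag(m_vals) + 0i
  Sp <- matrix(0 + 0i, n, n)
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      if (m_vals[r] == m_vals[c] + 1) {
        Sp[r, c] <- sqrt(S * (S + 1) - m_vals[c] * (m_vals[c] + 1))
      }
    }
  }
  Sm <- Conj(t(Sp))
  list(x = (Sp + Sm) / 2, y = -0.5i * (Sp - Sm), z = Sz)
}

oracle_rot <- function(alpha, beta, gamma) {
  # Z-Y-Z active, degrees
  d <- pi / 180
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  Rz(alpha * d) %*% Ry(beta * d) %*% Rz(gamma * d)
}

# Full dimer Hamiltonian assembled directly from Kronecker products,
# term by term (ZFS via explicit D-tensor sums, Zeeman, -2J exchange).
oracle_dimer_H <- function(S1, S2, D1, EoD1, eul1, D2, EoD2, eul2,
                           g1, g2, J, B, l) {
  m1 <- oracle_spin_mats(S1); m2 <- oracle_spin_mats(S2)
  n1 <- nrow(m1$z); n2 <- nrow(m2$z)
  I1 <- diag(n1) + 0i; I2 <- diag(n2) + 0i
  up1 <- list(kronecker(m1$x, I2), kronecker(m1$y, I2), kronecker(m1$z, I2))
  up2 <- list(kronecker(I1, m2$x), kronecker(I1, m2$y), kronecker(I1, m2$z))
  H <- matrix(0 + 0i, n1 * n2, n1 * n2)
  site_terms <- function(ops, D, EoD, eul, g) {
    E <- EoD * D
    Dp <- diag(c(-D / 3 + E, -D / 3 - E, 2 * D / 3))
    R <- oracle_rot(eul[1], eul[2], eul[3])
    Dt <- R %*% Dp %*% t(R)
    gt <- R %*% diag(rep(g, 3)) %*% t(R)
    out <- matrix(0 + 0i, n1 * n2, n1 * n2)
    for (u in 1:3) for (v in 1:3) {
      out <- out + Dt[u, v] * (ops[[u]] %*% ops[[v]])
    }
    for (u in 1:3) for (v in 1:3) {
      out <- out + BETA * B * l[u] * gt[u, v] * ops[[v]]
    }
    out
  }
  H <- H + site_terms(up1, D1, EoD1, eul1, g1)
  H <- H + site_terms(up2, D2, EoD2, eul2, g2)
  for (u in 1:3) H <- H - 2 * J * (up1[[u]] %*% up2[[u]])
  H
}

# --- plain-R powder average (slow, small grids only) -----------------------
# Riemann-sum orientation average of the C-term expression with per-state
# expectations from eigen(); no degeneracy handling needed at B > 0.
oracle_powder_intensity <- function(H_at, Sops, S_scale, M, B, T,
                                    n_th = 24, n_ph = 24) {
  th <- (seq_len(n_th) - 0.5) * pi / n_th
  ph <- (seq_len(n_ph) - 0.5) * 2 * pi / n_ph
  total <- 0
  for (a in th) {
    for (b in ph) {
      l <- c(sin(a) * cos(b), sin(a) * sin(b), cos(a))
      H <- H_at(B, l)
      ed <- eigen(H, symmetric = TRUE)
      ord <- order(ed$values)
      e <- ed$values[ord]; v <- ed$vectors[, ord, drop = FALSE]
      pop <- exp(-(e - e[1]) / (KB * T)); pop <- pop / sum(pop)
      sx <- Re(colSums(Conj(v) * (Sops$x %*% v)))
      sy <- Re(colSums(Conj(v) * (Sops$y %*% v)))
      sz <- Re(colSums(Conj(v) * (Sops$z %*% v)))
      term <- sum(pop * (l[1] * sx * M[3] + l[2] * sy * M[2] +
                           l[3] * sz * M[1]))
      total <- total + term * sin(a) * (pi / n_th) * (2 * pi / n_ph)
    }
  }
  total / (4 * pi * S_scale)
}

# --- one-electron l matrix elements ----------------------------------------
# Frozen from an independent symbolic ladder-operator derivation (real d
# orbitals expanded over |l=2,m>, Condon-Shortley phases). Entries are the
# imaginary parts of <row| l_u |col>; all elements are purely imaginary.
oracle_angmom_table <- function() {
  orbs <- c("d_xy", "d_xz", "d_yz", "d_z2", "d_x2-y2")
  mk <- function(entries) {
    M <- matrix(0, 5, 5, dimnames = list(orbs, orbs))
    for (e in entries) {
      M[e[[1]], e[[2]]] <- e[[3]]
      M[e[[2]], e[[1]]] <- -e[[3]]
    }
    M
  }
  s3 <- sqrt(3)
  list(
    x = mk(list(list("d_z2", "d_yz", s3), list("d_xz", "d_xy", 1),
                list("d_x2-y2", "d_yz", 1))),
    y = mk(list(list("d_xz", "d_z2", s3), list("d_xz", "d_x2-y2", -1),
                list("d_yz", "d_xy", -1))),
    z = mk(list(list("d_yz", "d_xz", 1), list("d_xy", "d_x2-y2", 2)))
  )
}

# --- shared fixtures --------------------------------------------------------
mono_system <- function(D = 28, EoD = 0, g = 2) {
  spin_system(spin_site(1, zfs_params(D = D, E_over_D = EoD), g = g))
}

dimer_system <- function() scenario_preset("complex2_dimer")$system

coarse_grid <- function() orientation_grid(12, 24)
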