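# Operator machinery: site spin operators in the product basis, the
# field-independent Hamiltonian H0 (ZFS + exchange) and the three Zeeman
# operators Z_u such that H(B, l) = H0 + B * (l_x Zx + l_y Zy + l_z Zz).

site_operators <- function(system) {
  ns <- n_sites(system)
  mats <- lapply(system$sites, function(s) spin_matrices(s$S))
  dims <- vapply(system$sites, function(s) as.integer(2 * s$S + 1), integer(1))
  if (ns == 1L) {
    mats
  } else {
    iA <- diag(dims[1]) + 0i
    iB <- diag(dims[2]) + 0i
    list(
      lapply(mats[[1]], function(m) kronecker(m, iB)),
      lapply(mats[[2]], function(m) kronecker(iA, m))
    )
  }
}

# H0, Zeeman operators and per-mode spin operators for a system.
system_operators <- function(system) {
  ops <- site_operators(system)
  n <- system$dim
  H0 <- matrix(0 + 0i, n, n)
  Z <- list(x = matrix(0 + 0i, n, n), y = matrix(0 + 0i, n, n),
            z = matrix(0 + 0i, n, n))
  for (i in seq_along(system$sites)) {
    site <- system$sites[[i]]
    Dm <- zfs_tensor(site$zfs)
    gm <- g_tensor(site)
    Sv <- ops[[i]]
    for (u in 1:3) {
      for (v in 1:3) {
        if (Dm[u, v] != 0) H0 <- H0 + Dm[u, v] * (Sv[[u]] %*% Sv[[v]])
        if (gm[u, v] != 0) Z[[u]] <- Z[[u]] + .BETA_CM1_T * gm[u, v] * Sv[[v]]
      }
    }
  }
  if (n_sites(system) == 2L) {
    c_ex <- exchange_prefactor(system$exchange)
    for (u in 1:3) H0 <- H0 + c_ex * (ops[[1]][[u]] %*% ops[[2]][[u]])
  }
  # Hermitize against roundoff
  H0 <- (H0 + Conj(t(H0))) / 2
  list(H0 = H0, Z = Z, site_ops = ops)
}

mode_operators <- function(system, mode = c("total", "site-A", "site-B"),
                           ops = NULL) {
  mode <- match.arg(mode)
  if (is.null(ops)) ops <- site_operators(system)
  if (n_sites(system) == 1L) {
    if (mode != "total") {
      stop("spin-operator mode '", mode,
           "' is only meaningful for two-site systems", call. = FALSE)
    }
    return(ops[[1]])
  }
  switch(mode,
    total    = list(x = ops[[1]]$x + ops[[2]]$x,
                    y = ops[[1]]$y + ops[[2]]$y,
                    z = ops[[1]]$z + ops[[2]]$z),
    `site-A` = ops[[1]],
    `site-B` = ops[[2]]
  )
}

#' Build the spin Hamiltonian matrix
#'
#' Assembles H = sum_i \[S_i . D_i . S_i + beta B l . g_i . S_i\] for one or
#' two spin sites, plus the isotropic Heisenberg exchange term (under the
#' stored convention, e.g. -2J S_A.S_B) for a dimer, in the Kronecker product
#' basis |M_A, M_B>. All energies in cm^-1, fields in Tesla.
#'
#' @param system a [spin_system()]
#' @param field a [field_vector()] (default: zero field)
#' @return A complex Hermitian matrix of dimension `system$dim`.
#' @examples
#' sys <- spin_system(spin_site(1, zfs_params(D = 28), g = 2))
#' eigen(build_hamiltonian(sys), only.values = TRUE)$values  # 56/3,56/3,-56/3*? gap 28
#' @export
build_hamiltonian <- function(system, field = field_vector(0)) {
  stopifnot(inherits(system, "spin_system"), inherits(field, "field_vector"))
  so <- system_operators(system)
  H <- so$H0 + field$B * (field$l[1] * so$Z$x + field$l[2] * so$Z$y +
                          field$l[3] * so$Z$z)
  (H + Conj(t(H))) / 2
}

#' Thermal sublevel energies, populations and spin expectation values
#'
#' Diagonalizes the spin Hamiltonian at the given field and returns the
#' sublevel energies (sorted ascending), Boltzmann populations at temperature
#' `T`, and the expectation values <s_x>, <s_y>, <s_z> of the selected spin
#' operators (total spin, or a single site's spin for a dimer) over each
#' eigenstate.
#'
#' Within degenerate eigen-subspaces (relevant at zero field) the expectation
#' values are replaced by the subspace average tr(P S_u P)/dim(P), so that
#' the arbitrary mixing a numerical diagonalizer picks inside a degenerate
#' block cannot leak into the result; time-reversal partners then cancel
#' exactly at B = 0.
#'
#' @param system a [spin_system()]
#' @param field a [field_vector()]
#' @param T temperature, Kelvin (> 0)
#' @param mode spin operators used for the expectation values: `"total"`
#'   (default), or `"site-A"` / `"site-B"` for a dimer
#' @param degeneracy_tol energy difference (cm^-1) below which two levels are
#'   treated as degenerate
#' @return An object of class `sublevels`: a list with `energies` (cm^-1),
#'   `states` (columns are eigenvectors), `populations` (summing to 1), and
#'   `spin_expectations` (matrix n x 3, columns x, y, z).
#' @examples
#' sys <- spin_system(spin_site(1, zfs_params(D = 28), g = 2))
#' sl <- thermal_sublevels(sys, field_vector(10), T = 20)
#' sl$populations
#' sl$spin_expectations
#' @export
thermal_sublevels <- function(system, field, T,
                              mode = c("total", "site-A", "site-B"),
                              degeneracy_tol = 1e-7) {
  stopifnot(inherits(system, "spin_system"), inherits(field, "field_vector"))
  if (!is.numeric(T) || length(T) != 1L || T <= 0) {
    stop("temperature must be a single value > 0", call. = FALSE)
  }
  mode <- match.arg(mode)
  H <- build_hamiltonian(system, field)
  ed <- eigen(H, symmetric = TRUE)
  idx <- order(ed$values)
  energies <- ed$values[idx]
  states <- ed$vectors[, idx, drop = FALSE]

  pop <- boltzmann_populations(energies, T)

  sop <- mode_operators(system, mode)
  exp_mat <- matrix(0, length(energies), 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  for (u in 1:3) {
    Ov <- sop[[u]] %*% states
    exp_mat[, u] <- Re(colSums(Conj(states) * Ov))
  }
  # subspace-average within degenerate groups
  grp <- cumsum(c(1, diff(energies) > degeneracy_tol))
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) > 1L) {
      exp_mat[sel, ] <- matrix(colMeans(exp_mat[sel, , drop = FALSE]),
                               nrow = sum(sel), ncol = 3, byrow = TRUE)
    }
  }
  structure(
    list(energies = energies, states = states, populations = pop,
         spin_expectations = exp_mat, T = T, field = field, mode = mode),
    class = "sublevels"
  )
}

boltzmann_populations <- function(energies, T) {
  w <- exp(-(energies - min(energies)) / (.KB_CM1_K * T))
  w / sum(w)
}

#' @export
print.sublevels <- function(x, ...) {
  cat(sprintf("<sublevels at B = %g T, T = %g K, mode = %s>\n",
              x$field$B, x$T, x$mode))
  df <- data.frame(energy_cm1 = x$energies, population = x$populations,
                   round(x$spin_expectations, 6))
  print(df, ...)
  invisible(x)
}

# Total spin quantum number of the zero-field ground multiplet, used as the
# 1/S normalization of the C-term intensity expression. Determined
# numerically from <S_tot^2> averaged over the (possibly degenerate)
# zero-field ground subspace.
ground_total_spin <- function(system) {
  if (n_sites(system) == 1L) return(system$sites[[1]]$S)
  so <- system_operators(system)
  Stot <- mode_operators(system, "total", so$site_ops)
  S2 <- Stot$x %*% Stot$x + Stot$y %*% Stot$y + Stot$z %*% Stot$z
  ed <- eigen(so$H0, symmetric = TRUE)
  idx <- order(ed$values)
  e <- ed$values[idx]
  v <- ed$vectors[, idx, drop = FALSE]
  sel <- e - e[1] < 1e-6
  vv <- v[, sel, drop = FALSE]
  s2 <- mean(Re(colSums(Conj(vv) * (S2 %*% vv))))
  # solve S(S+1) = s2 and snap to the nearest half-integer
  S <- (-1 + sqrt(1 + 4 * s2)) / 2
  round(2 * S) / 2
}
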