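#' Spin angular-momentum matrices
#'
#' Standard spin operators S_x, S_y, S_z in the |S, M> basis ordered
#' M = S, S-1, ..., -S, built from the ladder operators
#' S+|S,M> = sqrt(S(S+1) - M(M+1)) |S,M+1>. They satisfy the angular
#' momentum algebra \[S_x, S_y\] = i S_z and
#' S_x^2 + S_y^2 + S_z^2 = S(S+1) I.
#'
#' @param S spin quantum number, non-negative half-integer
#' @return A list with complex matrices `x`, `y`, `z` of dimension 2S+1.
#' @examples
#' spin_matrices(1)$z          # diag(1, 0, -1)
#' spin_matrices(1/2)$x        # Pauli sigma_x / 2
#' @export
spin_matrices <- function(S) {
  check_spin(S)
  n <- as.integer(round(2 * S + 1))
  M <- seq(S, -S, by = -1)
  Sz <- diag(M, n, n) + 0i
  Sp <- matrix(0 + 0i, n, n)
  if (n > 1L) {
    # S+ couples |S, M> -> |S, M+1>: row index of M+1 is one above M
    for (k in 2:n) {
      m <- M[k]
      Sp[k - 1L, k] <- sqrt(S * (S + 1) - m * (m + 1))
    }
  }
  Sm <- Conj(t(Sp))
  list(
    x = (Sp + Sm) / 2,
    y = (Sp - Sm) / (2i),
    z = Sz
  )
}

#' Rotation matrix from Z-Y-Z Euler angles
#'
#' Active rotation `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`, angles in degrees.
#'
#' @param euler three angles (degrees)
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
euler_matrix <- function(euler) {
  stopifnot(is.numeric(euler), length(euler) == 3L)
  a <- euler * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a[1]) %*% ry(a[2]) %*% rz(a[3])
}

#' Zero-field-splitting tensor in the molecular frame
#'
#' Builds the traceless symmetric ZFS tensor whose principal values are
#' (-D/3 + E, -D/3 - E, 2D/3) — the tensor form of
#' D\[S_z^2 - S(S+1)/3\] + E(S_x^2 - S_y^2) — and rotates it into the
#' molecular frame by the Euler angles stored in the parameter object:
#' `R %*% D_principal %*% t(R)`.
#'
#' @param zfs a [zfs_params()] object
#' @return A 3x3 symmetric traceless matrix, cm^-1.
#' @examples
#' zfs_tensor(zfs_params(D = 28))   # diag(-28/3, -28/3, 56/3)
#' @export
zfs_tensor <- function(zfs) {
  stopifnot(inherits(zfs, "zfs_params"))
  D <- zfs$D
  E <- zfs$E_over_D * D
  Dp <- diag(c(-D / 3 + E, -D / 3 - E, 2 * D / 3))
  R <- euler_matrix(zfs$euler)
  R %*% Dp %*% t(R)
}

# g tensor in the molecular frame; principal g-values co-rotate with the ZFS
# principal axes of the same site.
g_tensor <- function(site) {
  R <- euler_matrix(site$zfs$euler)
  R %*% diag(site$g) %*% t(R)
}

#' Magnetic field vector
#'
#' A field of given magnitude along the direction with polar angles
#' (theta, phi) in the molecular frame; the direction cosines
#' l = (sin(theta)cos(phi), sin(theta)sin(phi), cos(theta)) satisfy |l| = 1.
#'
#' @param B field magnitude, Tesla (non-negative)
#' @param theta,phi polar angles, radians
#' @return An object of class `field_vector` with elements `B`, `theta`,
#'   `phi` and the unit direction cosines `l`.
#' @examples
#' field_vector(10)          # 10 T along the molecular z axis
#' @export
field_vector <- function(B, theta = 0, phi = 0) {
  stopifnot(is.numeric(B), length(B) == 1L, is.finite(B))
  if (B < 0) stop("field magnitude must be non-negative", call. = FALSE)
  l <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  structure(list(B = B, theta = theta, phi = phi, l = l),
            class = "field_vector")
}
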