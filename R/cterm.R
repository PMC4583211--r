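#' Quadrature grid over field orientations
#'
#' Powder averaging integrates the molecular response over all orientations
#' of the applied field in the molecular frame. The grid is a tensor product
#' of Gauss-Legendre nodes in cos(theta) with a uniform (trapezoidal, exact
#' for trigonometric polynomials) grid in phi; the weights sum to 4*pi.
#' The default density (32 x 64) is converged to better than 1e-6 relative
#' for the smooth integrands that arise here; it can be lowered for
#' iterative fitting.
#'
#' @param n_theta number of Gauss-Legendre nodes in cos(theta)
#' @param n_phi number of uniform nodes in phi
#' @return An object of class `orientation_grid`: a matrix with columns
#'   `lx`, `ly`, `lz`, `w`.
#' @examples
#' g <- orientation_grid(8, 16)
#' sum(g[, "w"]) / (4 * pi)   # 1
#' @export
orientation_grid <- function(n_theta = 32, n_phi = 64) {
  stopifnot(n_theta >= 2, n_phi >= 2)
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x                      # cos(theta)
  wt <- gl$w
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  wphi <- rep(2 * pi / n_phi, n_phi)
  nodes <- cbind(
    lx = as.vector(outer(st, cos(phi))),
    ly = as.vector(outer(st, sin(phi))),
    lz = rep(ct, times = n_phi),
    w  = as.vector(outer(wt, wphi))
  )
  structure(nodes, class = c("orientation_grid", "matrix"),
            n_theta = n_theta, n_phi = n_phi)
}

#' Effective transition dipole moment products
#'
#' The three signed products M_xy, M_xz, M_yz (arbitrary units) that govern
#' the C-term intensity contributed by the spin expectation values along z,
#' y and x respectively, together with an overall per-band scale `gamma`.
#' Observable intensities depend only on the products gamma * M_vw, so
#' (gamma, M) -> (gamma/c, c*M) leaves every prediction unchanged.
#'
#' @param M_xy,M_xz,M_yz signed products
#' @param gamma overall scale
#' @param site for a dimer, which site's spin operators the band couples to:
#'   `"total"`, `"A"` or `"B"`
#' @return An object of class `transition_moments`.
#' @examples
#' transition_moments(0, 1, 1)   # a purely z-polarized band
#' @export
transition_moments <- function(M_xy, M_xz, M_yz, gamma = 1,
                               site = c("total", "A", "B")) {
  site <- match.arg(site)
  m <- c(M_xy = M_xy, M_xz = M_xz, M_yz = M_yz)
  stopifnot(is.numeric(m), all(is.finite(m)), is.finite(gamma))
  structure(list(M_xy = M_xy, M_xz = M_xz, M_yz = M_yz, gamma = gamma,
                 site = site),
            class = "transition_moments")
}

moments_mode <- function(moments) {
  switch(moments$site, total = "total", A = "site-A", B = "site-B")
}

#' Powder-averaged C-term design matrix
#'
#' The C-term intensity at fixed spin-Hamiltonian parameters is linear in
#' the three moment products:
#' I = gamma * (A_x M_yz + A_y M_xz + A_z M_xy), with
#' A_u = 1/(4 pi S) * integral over orientations of
#' w * l_u * sum_i N_i <s_u>_i. This function returns the n x 3 matrix of
#' A_u values for a vector of (B, T) points, using exact diagonalization at
#' every quadrature node (no linear-response shortcut).
#'
#' @param system a [spin_system()]
#' @param B,T numeric vectors of equal length (Tesla, Kelvin)
#' @param mode spin-operator set: `"total"`, `"site-A"`, `"site-B"`
#' @param grid an [orientation_grid()]
#' @return Matrix with columns `A_x`, `A_y`, `A_z`.
#' @export
cterm_design <- function(system, B, T, mode = "total",
                         grid = orientation_grid()) {
  stopifnot(inherits(system, "spin_system"), length(B) == length(T))
  if (any(T <= 0)) stop("all temperatures must be > 0", call. = FALSE)
  if (any(B < 0)) stop("field magnitudes must be >= 0", call. = FALSE)
  cterm_design_multi(system, B, T, rep(mode, length(B)), grid)
}

# multi-mode variant: `modes` gives the spin-operator set per point, so
# bands coupling to different site operators share every diagonalization
cterm_design_multi <- function(system, B, T, modes, grid) {
  so <- system_operators(system)
  umodes <- unique(modes)
  ops <- lapply(umodes, function(m) mode_operators(system, m, so$site_ops))
  idx <- match(modes, umodes) - 1L
  S_scale <- ground_total_spin(system)
  A <- powder_design_cpp(so$H0, so$Z$x, so$Z$y, so$Z$z, ops,
                         unclass(grid)[, c("lx", "ly", "lz", "w"),
                                       drop = FALSE],
                         as.numeric(B), as.numeric(T), as.integer(idx),
                         S_scale, .KB_CM1_K, 1e-7)
  colnames(A) <- c("A_x", "A_y", "A_z")
  A
}

#' Powder-averaged VTVH MCD C-term intensity
#'
#' Simulates the saturation-magnetization C-term intensity
#' I = gamma/(4 pi S) * integral over the sphere of
#' sum_i N_i (l_x <s_x>_i M_yz + l_y <s_y>_i M_xz + l_z <s_z>_i M_xy) dOmega,
#' where N_i are Boltzmann populations of the ground-state magnetic
#' sublevels at each field orientation, obtained by exact diagonalization.
#' The intensity is odd in the field and vanishes at B = 0.
#'
#' @param system a [spin_system()]
#' @param moments a [transition_moments()]
#' @param B,T field (Tesla) and temperature (Kelvin); vectors of equal
#'   length (or one of them scalar, recycled)
#' @param grid an [orientation_grid()]
#' @return Numeric vector of intensities (arbitrary units).
#' @examples
#' sys <- spin_system(spin_site(1/2, g = 2))
#' m <- transition_moments(1, 0, 0)
#' powder_cterm_intensity(sys, m, B = c(0, 5), T = 2)
#' @export
powder_cterm_intensity <- function(system, moments, B, T,
                                   grid = orientation_grid()) {
  stopifnot(inherits(moments, "transition_moments"))
  mm <- c(moments$M_xy, moments$M_xz, moments$M_yz)
  if (all(mm == 0)) stop("all transition moment products are zero", call. = FALSE)
  n <- max(length(B), length(T))
  B <- rep_len(B, n); T <- rep_len(T, n)
  # negative B: use oddness I(-B) = -I(B)
  sgn <- ifelse(B < 0, -1, 1)
  A <- cterm_design(system, abs(B), T, mode = moments_mode(moments),
                    grid = grid)
  unname(sgn * moments$gamma *
           (A[, "A_x"] * moments$M_yz + A[, "A_y"] * moments$M_xz +
            A[, "A_z"] * moments$M_xy))
}

#' Isothermal VTVH magnetization curves
#'
#' One saturation-magnetization curve per temperature over a common field
#' grid, with the dimensionless abscissa beta*B/(k*T) attached. Curves can
#' be returned raw or normalized to the maximum absolute intensity of each
#' isotherm (the form in which nesting is judged).
#'
#' @param system a [spin_system()]
#' @param moments a [transition_moments()]
#' @param fields numeric vector of fields, Tesla
#' @param temps numeric vector of temperatures, Kelvin
#' @param grid an [orientation_grid()]
#' @param normalize `"raw"` or `"max"`
#' @return A data frame of class `vtvh_curves` with columns `B_T`, `T_K`,
#'   `beta_B_over_kT`, `intensity`; the normalization mode is stored in
#'   attribute `normalize`.
#' @examples
#' sys <- spin_system(spin_site(1, zfs_params(D = 28), g = 2))
#' cv <- vtvh_curves(sys, transition_moments(0, 1, 1),
#'                   fields = seq(0, 10, 2), temps = c(2, 10),
#'                   grid = orientation_grid(8, 16))
#' @export
vtvh_curves <- function(system, moments, fields, temps,
                        grid = orientation_grid(),
                        normalize = c("raw", "max")) {
  normalize <- match.arg(normalize)
  stopifnot(length(fields) >= 1, length(temps) >= 1)
  pts <- expand.grid(B_T = fields, T_K = temps)
  I <- powder_cterm_intensity(system, moments, pts$B_T, pts$T_K, grid = grid)
  if (normalize == "max") {
    for (tt in unique(pts$T_K)) {
      sel <- pts$T_K == tt
      mx <- max(abs(I[sel]))
      if (mx > 0) I[sel] <- I[sel] / mx
    }
  }
  out <- data.frame(B_T = pts$B_T, T_K = pts$T_K,
                    beta_B_over_kT = .BETA_CM1_T * pts$B_T /
                      (.KB_CM1_K * pts$T_K),
                    intensity = I)
  structure(out, class = c("vtvh_curves", "data.frame"),
            normalize = normalize)
}

#' Closed-form S = 1/2 saturation curve
#'
#' For an isotropic S = 1/2 ground state the powder magnetization follows a
#' hyperbolic tangent, tanh(g * beta * B / (2 k T)); isotherms at all
#' temperatures overlay when plotted against beta*B/(k*T). Used as an
#' independent oracle for the numerical powder average.
#'
#' @param g isotropic g-value
#' @param B field, Tesla (>= 0)
#' @param T temperature, Kelvin (> 0)
#' @return tanh(g beta B / 2 k T)
#' @examples
#' s_half_closed_form(2, 7, 2)
#' @export
s_half_closed_form <- function(g, B, T) {
  stopifnot(all(B >= 0))
  if (any(T <= 0)) stop("temperature must be > 0", call. = FALSE)
  tanh(g * .BETA_CM1_T * B / (2 * .KB_CM1_K * T))
}

#' Fractional polarizations from moment products
#'
#' Percentage of a band's C-term intensity polarized along each molecular
#' axis:
#' %x = 100 (M_xy M_xz)^2 / \[(M_xy M_xz)^2 + (M_xy M_yz)^2 + (M_xz M_yz)^2\],
#' and cyclic permutations for y and z. Homogeneous of degree zero in the
#' products, so any common rescaling leaves the fractions unchanged.
#'
#' @param moments a [transition_moments()] (or three numbers
#'   `c(M_xy, M_xz, M_yz)`)
#' @return Named vector `c(x =, y =, z =)` in percent, summing to 100.
#' @examples
#' fractional_polarizations(transition_moments(0, 1, 1))  # pure z
#' fractional_polarizations(c(1, 1, 1))                   # 1/3 each
#' @export
fractional_polarizations <- function(moments) {
  if (inherits(moments, "transition_moments")) {
    m <- c(moments$M_xy, moments$M_xz, moments$M_yz)
  } else {
    stopifnot(is.numeric(moments), length(moments) == 3L)
    m <- moments
  }
  if (sum(m != 0) < 2L) {
    stop("fractional polarizations are undefined with fewer than two ",
         "nonzero moment products", call. = FALSE)
  }
  px <- (m[1] * m[2])^2
  py <- (m[1] * m[3])^2
  pz <- (m[2] * m[3])^2
  tot <- px + py + pz
  100 * c(x = px, y = py, z = pz) / tot
}

#' Nesting metric of a family of isotherms
#'
#' Quantifies the failure of isothermal magnetization curves to superimpose
#' when plotted against beta*B/(k*T). For every pair of isotherms with an
#' overlapping abscissa range, both curves are normalized to their value at
#' the upper end of the common range (so curves that are the same function
#' of beta*B/kT coincide exactly) and the maximum absolute difference over
#' that range is taken; the metric is the largest such spread over all
#' overlapping pairs. Zero (to quadrature accuracy) for an isotropic
#' S = 1/2 system, whose isotherms all follow the same hyperbolic tangent;
#' strictly positive for S >= 1 with sizable zero-field splitting.
#'
#' Widely separated temperatures may have no common beta*B/kT range over a
#' finite field window; such pairs are skipped (an error is raised only if
#' no pair overlaps).
#'
#' @param curves a `vtvh_curves` data frame (any normalization)
#' @param n_interp number of interpolation points per pair
#' @return Maximum normalized spread between overlapping isotherm pairs.
#' @export
nesting_metric <- function(curves, n_interp = 50) {
  stopifnot(is.data.frame(curves),
            all(c("beta_B_over_kT", "intensity", "T_K") %in% names(curves)))
  temps <- sort(unique(curves$T_K))
  if (length(temps) < 2L) return(0)
  iso <- lapply(temps, function(tt) {
    sel <- curves$T_K == tt
    o <- order(curves$beta_B_over_kT[sel])
    list(x = curves$beta_B_over_kT[sel][o], y = curves$intensity[sel][o])
  })
  spread <- -Inf
  for (i in seq_len(length(temps) - 1L)) {
    for (j in (i + 1L):length(temps)) {
      lo <- max(min(iso[[i]]$x), min(iso[[j]]$x))
      hi <- min(max(iso[[i]]$x), max(iso[[j]]$x))
      if (hi <= lo) next
      xs <- seq(lo, hi, length.out = n_interp)
      yi <- stats::approx(iso[[i]]$x, iso[[i]]$y, xout = xs)$y
      yj <- stats::approx(iso[[j]]$x, iso[[j]]$y, xout = xs)$y
      # anchor both curves at the common endpoint
      if (abs(yi[n_interp]) < 1e-300 || abs(yj[n_interp]) < 1e-300) next
      spread <- max(spread, max(abs(yi / yi[n_interp] - yj / yj[n_interp])))
    }
  }
  if (!is.finite(spread)) {
    stop("no pair of isotherms shares an overlapping beta*B/kT range",
         call. = FALSE)
  }
  spread
}
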