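#' Zero-field-splitting parameters
#'
#' Container for the axial (`D`) and rhombic (`E/D`) zero-field-splitting
#' parameters of a spin centre together with the orientation of the ZFS
#' tensor principal axes in the molecular frame.
#'
#' Euler angles follow the Z-Y-Z convention with *active* rotations, in
#' degrees: the principal-axis tensor is rotated by `Rz(alpha) Ry(beta)
#' Rz(gamma)` into the molecular frame.
#'
#' @param D axial ZFS parameter, cm^-1
#' @param E_over_D rhombicity, dimensionless, in [0, 1/3]
#' @param euler three Euler angles (degrees), Z-Y-Z active convention
#' @return An object of class `zfs_params`.
#' @examples
#' zfs_params(D = 28, E_over_D = 0)
#' zfs_params(D = 5.3, E_over_D = 0.30, euler = c(90, 0, 0))
#' @export
zfs_params <- function(D = 0, E_over_D = 0, euler = c(0, 0, 0)) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D))
  stopifnot(is.numeric(E_over_D), length(E_over_D) == 1L)
  if (E_over_D < 0 || E_over_D > 1 / 3 + 1e-12) {
    stop("E_over_D must lie in [0, 1/3]", call. = FALSE)
  }
  stopifnot(is.numeric(euler), length(euler) == 3L, all(is.finite(euler)))
  structure(
    list(D = D, E_over_D = min(E_over_D, 1 / 3), euler = as.numeric(euler)),
    class = "zfs_params"
  )
}

#' A single spin centre
#'
#' @param S spin quantum number; any non-negative half-integer
#' @param zfs a [zfs_params()] object
#' @param g three principal g-values, diagonal in the site ZFS frame and
#'   co-rotating with it; a scalar is recycled (isotropic g)
#' @return An object of class `spin_site`.
#' @examples
#' spin_site(S = 1, zfs = zfs_params(D = 28), g = 2.00)
#' @export
spin_site <- function(S, zfs = zfs_params(), g = c(2, 2, 2)) {
  check_spin(S)
  stopifnot(inherits(zfs, "zfs_params"))
  if (length(g) == 1L) g <- rep(g, 3L)
  stopifnot(is.numeric(g), length(g) == 3L, all(g > 0))
  structure(list(S = S, zfs = zfs, g = as.numeric(g)), class = "spin_site")
}

check_spin <- function(S) {
  if (!is.numeric(S) || length(S) != 1L || S < 0 ||
      abs(2 * S - round(2 * S)) > 1e-9) {
    stop("S must be a non-negative half-integer", call. = FALSE)
  }
  invisible(S)
}

#' Isotropic Heisenberg exchange coupling
#'
#' Two sign conventions for the bilinear exchange Hamiltonian are supported:
#' `"minus2J"` (H_ex = -2J S_A.S_B; J > 0 ferromagnetic) and `"plusJ"`
#' (H_ex = +J S_A.S_B; J < 0 ferromagnetic). The two describe identical
#' physics with J_plusJ = -2 J_minus2J.
#'
#' @param J exchange constant, cm^-1
#' @param convention `"minus2J"` or `"plusJ"`
#' @return An object of class `exchange_coupling`.
#' @examples
#' exchange_coupling(35)                      # ferromagnetic, -2J convention
#' convert_exchange_convention(exchange_coupling(35), "plusJ")
#' @export
exchange_coupling <- function(J, convention = c("minus2J", "plusJ")) {
  stopifnot(is.numeric(J), length(J) == 1L, is.finite(J))
  convention <- match.arg(convention)
  structure(list(J = J, convention = convention), class = "exchange_coupling")
}

#' @rdname exchange_coupling
#' @param coupling an `exchange_coupling` object
#' @param target target convention, `"minus2J"` or `"plusJ"`
#' @export
convert_exchange_convention <- function(coupling,
                                        target = c("minus2J", "plusJ")) {
  stopifnot(inherits(coupling, "exchange_coupling"))
  target <- match.arg(target)
  if (identical(coupling$convention, target)) return(coupling)
  # J * S_A.S_B == -2 * (-J/2) * S_A.S_B; the map J -> -2J (and its inverse
  # J -> -J/2) preserves the Hamiltonian spectrum exactly.
  J_new <- if (target == "plusJ") -2 * coupling$J else -coupling$J / 2
  exchange_coupling(J_new, target)
}

# signed prefactor c such that H_ex = c * S_A.S_B
exchange_prefactor <- function(coupling) {
  switch(coupling$convention,
    minus2J = -2 * coupling$J,
    plusJ   = coupling$J
  )
}

#' A spin system: one site, or two exchange-coupled sites
#'
#' For a dimer the Hamiltonian lives in the Kronecker-product basis
#' |M_A, M_B> of dimension (2S_A+1)(2S_B+1), with site A varying slowest.
#'
#' @param sites a `spin_site` or a list of one or two `spin_site` objects
#' @param exchange an [exchange_coupling()]; required when two sites are
#'   given, must be absent for a single site
#' @return An object of class `spin_system` with a `dim` field equal to the
#'   product of the site multiplicities.
#' @examples
#' # mononuclear S = 1 iron(IV)-oxo with D = +28 cm^-1
#' spin_system(spin_site(1, zfs_params(D = 28), g = 2))
#'
#' # ferromagnetically coupled diiron(IV) dimer
#' spin_system(
#'   list(spin_site(1, zfs_params(D = 28), g = 2),
#'        spin_site(1, zfs_params(D = 5.3, E_over_D = 0.30,
#'                                euler = c(90, 0, 0)), g = 2)),
#'   exchange = exchange_coupling(35, "minus2J")
#' )
#' @export
spin_system <- function(sites, exchange = NULL) {
  if (inherits(sites, "spin_site")) sites <- list(sites)
  stopifnot(is.list(sites), length(sites) %in% c(1L, 2L))
  lapply(sites, function(s) stopifnot(inherits(s, "spin_site")))
  if (length(sites) == 2L) {
    if (is.null(exchange)) {
      stop("a two-site system requires an exchange coupling", call. = FALSE)
    }
    stopifnot(inherits(exchange, "exchange_coupling"))
  } else if (!is.null(exchange)) {
    stop("exchange coupling given for a single-site system", call. = FALSE)
  }
  dim <- prod(vapply(sites, function(s) 2 * s$S + 1, numeric(1)))
  structure(
    list(sites = sites, exchange = exchange, dim = as.integer(round(dim))),
    class = "spin_system"
  )
}

n_sites <- function(system) length(system$sites)

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system: %d site(s), basis dimension %d>\n",
              n_sites(x), x$dim))
  for (i in seq_along(x$sites)) {
    s <- x$sites[[i]]
    cat(sprintf(
      "  site %s: S = %g, D = %g cm^-1, E/D = %g, euler = (%g, %g, %g) deg, g = (%g, %g, %g)\n",
      LETTERS[i], s$S, s$zfs$D, s$zfs$E_over_D,
      s$zfs$euler[1], s$zfs$euler[2], s$zfs$euler[3],
      s$g[1], s$g[2], s$g[3]
    ))
  }
  if (!is.null(x$exchange)) {
    cat(sprintf("  exchange: J = %g cm^-1 (%s convention)\n",
                x$exchange$J, x$exchange$convention))
  }
  invisible(x)
}

#' Serialize a spin system to a plain list / file and back
#'
#' The list form round-trips through YAML or JSON unchanged, so a complete
#' system definition (spins, D, E/D, Euler angles, g, J, convention) can be
#' stored alongside data files. Unknown keys are rejected on reading.
#'
#' @param system a `spin_system`
#' @return `spin_system_to_list()`: a plain nested list;
#'   `spin_system_from_list()`: a `spin_system`.
#' @examples
#' sys <- spin_system(spin_site(1, zfs_params(D = 28)))
#' identical(spin_system_from_list(spin_system_to_list(sys)), sys)
#' @export
spin_system_to_list <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  out <- list(
    sites = lapply(system$sites, function(s) {
      list(S = s$S, D = s$zfs$D, E_over_D = s$zfs$E_over_D,
           euler = s$zfs$euler, g = s$g)
    })
  )
  if (!is.null(system$exchange)) {
    out$exchange <- list(J = system$exchange$J,
                         convention = system$exchange$convention)
  }
  out
}

#' @rdname spin_system_to_list
#' @param x a plain list as produced by `spin_system_to_list()`
#' @export
spin_system_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$sites))
  extra <- setdiff(names(x), c("sites", "exchange"))
  if (length(extra)) {
    stop("unknown keys in spin system definition: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  sites <- lapply(x$sites, function(s) {
    extra <- setdiff(names(s), c("S", "D", "E_over_D", "euler", "g"))
    if (length(extra)) {
      stop("unknown keys in site definition: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    spin_site(
      S = s$S,
      zfs = zfs_params(D = s$D %||% 0, E_over_D = s$E_over_D %||% 0,
                       euler = s$euler %||% c(0, 0, 0)),
      g = s$g %||% c(2, 2, 2)
    )
  })
  exch <- if (!is.null(x$exchange)) {
    exchange_coupling(x$exchange$J, x$exchange$convention %||% "minus2J")
  }
  spin_system(sites, exchange = exch)
}

#' @rdname spin_system_to_list
#' @param path file path ending in `.yaml`, `.yml` or `.json`
#' @export
write_spin_system <- function(system, path) {
  x <- spin_system_to_list(system)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname spin_system_to_list
#' @export
read_spin_system <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # JSON simplification can turn the site list into a data frame; normalize
  if (is.data.frame(x$sites)) {
    x$sites <- lapply(seq_len(nrow(x$sites)), function(i) {
      as.list(x$sites[i, , drop = FALSE])
    })
    x$sites <- lapply(x$sites, function(s) {
      lapply(s, function(v) if (is.list(v)) unlist(v) else v)
    })
  }
  spin_system_from_list(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
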