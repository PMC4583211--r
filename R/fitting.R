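# Fitting of effective transition dipole moment products and
# spin-Hamiltonian parameters to multi-wavelength VTVH datasets.
#
# The C-term intensity is exactly linear in the three products gamma*M_vw at
# fixed spin-Hamiltonian parameters, so the per-band moment estimation is a
# weighted linear least-squares problem solved exactly by QR (variable
# projection). Only the spin-Hamiltonian parameters require a nonlinear
# outer optimization, which is multi-started from a seeded Latin hypercube
# because the problem is documented to possess many local minima.

.SH_PAR_NAMES <- c("D_1", "EoD_1", "D_2", "EoD_2", "J")

.default_bounds <- function() {
  list(
    lower = c(D_1 = -60, EoD_1 = 0, D_2 = -60, EoD_2 = 0, J = 1),
    upper = c(D_1 = 60, EoD_1 = 1 / 3, D_2 = 60, EoD_2 = 1 / 3, J = 120)
  )
}

#' Specification of a VTVH fit
#'
#' Declares which spin-Hamiltonian parameters are free (per-band transition
#' moment products are always estimated, by exact linear least squares),
#' their finite box bounds, the number of multi-start restarts and the
#' random seed that makes the restarts reproducible.
#'
#' Parameter names: `D_1`, `EoD_1` (site A), `D_2`, `EoD_2` (site B), `J`.
#' Rhombicities are always bounded within \[0, 1/3\].
#'
#' @param free character vector of free parameter names (may be empty)
#' @param lower,upper named numeric vectors overriding the default bounds
#' @param n_starts number of Latin-hypercube restarts
#' @param seed integer seed for the restart design
#' @return An object of class `fit_spec`.
#' @examples
#' fit_spec(free = c("D_2", "EoD_2"), n_starts = 8, seed = 1)
#' @export
fit_spec <- function(free = character(), lower = NULL, upper = NULL,
                     n_starts = 32, seed = 1) {
  stopifnot(is.character(free))
  bad <- setdiff(free, .SH_PAR_NAMES)
  if (length(bad)) {
    stop("unknown free parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  b <- .default_bounds()
  lo <- b$lower; up <- b$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  lo["EoD_1"] <- max(lo["EoD_1"], 0); up["EoD_1"] <- min(up["EoD_1"], 1 / 3)
  lo["EoD_2"] <- max(lo["EoD_2"], 0); up["EoD_2"] <- min(up["EoD_2"], 1 / 3)
  if (length(free) && any(!is.finite(lo[free]) | !is.finite(up[free]))) {
    stop("every free parameter needs finite bounds", call. = FALSE)
  }
  if (length(free) && any(lo[free] >= up[free])) {
    stop("lower bounds must be below upper bounds", call. = FALSE)
  }
  structure(list(free = free, lower = lo, upper = up,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fit_spec")
}

# extract / apply the SH parameter vector of a system
system_parameters <- function(system) {
  p <- c(D_1 = system$sites[[1]]$zfs$D, EoD_1 = system$sites[[1]]$zfs$E_over_D)
  if (n_sites(system) == 2L) {
    p <- c(p, D_2 = system$sites[[2]]$zfs$D,
           EoD_2 = system$sites[[2]]$zfs$E_over_D, J = system$exchange$J)
  }
  p
}

apply_parameters <- function(system, par) {
  for (nm in names(par)) {
    val <- unname(par[[nm]])
    switch(nm,
      D_1 = { system$sites[[1]]$zfs$D <- val },
      EoD_1 = { system$sites[[1]]$zfs$E_over_D <- val },
      D_2 = { system$sites[[2]]$zfs$D <- val },
      EoD_2 = { system$sites[[2]]$zfs$E_over_D <- val },
      J = { system$exchange$J <- val },
      stop("unknown parameter: ", nm, call. = FALSE)
    )
  }
  system
}

# Exact weighted linear LSQ of the moment products for every dataset at
# fixed SH parameters. Returns per-band coefficients and the total SSE.
profile_moments <- function(datasets, system, grid) {
  sites <- vapply(datasets, dataset_site, character(1))
  modes <- c(total = "total", A = "site-A", B = "site-B")[sites]
  nk <- vapply(datasets, nrow, integer(1))
  Aall <- cterm_design_multi(
    system,
    unlist(lapply(datasets, function(d) d$B_T)),
    unlist(lapply(datasets, function(d) d$T_K)),
    rep(modes, nk), grid
  )
  designs <- vector("list", length(datasets))
  off <- 0L
  for (k in seq_along(datasets)) {
    designs[[k]] <- Aall[off + seq_len(nk[k]), , drop = FALSE]
    off <- off + nk[k]
  }
  sse <- 0
  coefs <- vector("list", length(datasets))
  degenerate <- logical(length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    w <- dataset_weights(d)
    A <- designs[[k]]
    y <- d$intensity
    sw <- sqrt(w)
    # minimum-norm weighted least squares via SVD: powder symmetry can make
    # design columns exactly collinear (e.g. A_x = A_y for an axial system),
    # in which case the symmetric split is the physically sensible gauge
    cf <- pseudo_solve(A * sw, y * sw)
    if (all(abs(y) < 1e-14) || all(abs(cf) < 1e-12)) degenerate[k] <- TRUE
    coefs[[k]] <- cf
    sse <- sse + sum((y * sw - (A * sw) %*% cf)^2)
  }
  list(coefficients = coefs, sse = sse, designs = designs,
       degenerate = degenerate)
}

# Minimum-norm least-squares solution of A c = y by truncated SVD.
# Directions with singular values below rtol * max(sv) are discarded: powder
# quasi-symmetries (e.g. an axial system, where the x and y design columns
# coincide) otherwise let the solver amplify quadrature-level differences
# into enormous unphysical moment amplitudes that overfit the noise. The
# threshold sits well above numerical noise (~1e-8 relative) and well below
# the smallest physically resolved anisotropy directions (~1e-3 relative
# for E/D of a few hundredths).
pseudo_solve <- function(A, y, rtol = 1e-4) {
  sv <- svd(A)
  d <- sv$d
  keep <- d > rtol * max(d, 0)
  if (!any(keep)) return(numeric(ncol(A)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / d[keep]))
}

# map linear coefficients (c_x, c_y, c_z) multiplying (A_x, A_y, A_z),
# i.e. (gamma*M_yz, gamma*M_xz, gamma*M_xy), to a transition_moments object
# under the sign gauge M_xz >= 0
coef_to_moments <- function(cf, site) {
  gamma <- if (cf[2] < 0) -1 else 1
  transition_moments(M_xy = unname(cf[3]) / gamma,
                     M_xz = unname(cf[2]) / gamma,
                     M_yz = unname(cf[1]) / gamma,
                     gamma = gamma, site = site)
}

#' Fit transition moment products to VTVH data at fixed spin Hamiltonian
#'
#' Estimates the signed products (M_xy, M_xz, M_yz) and scale gamma for each
#' band (dataset) by exact weighted linear least squares against the powder
#' C-term design of the fixed spin system. Because the model is linear in
#' gamma*M_vw, the global optimum is found in closed form; the sign gauge
#' M_xz >= 0 (absorbing the indeterminate overall sign into gamma) makes the
#' reported products unique.
#'
#' @param datasets a `vtvh_dataset` or list of them
#' @param system a fully specified [spin_system()]
#' @param grid an [orientation_grid()]
#' @return An object of class `moment_fit`: per-band [transition_moments()],
#'   fractional polarizations, the weighted SSE, and degeneracy flags
#'   (all-zero data yields zero products, flagged).
#' @export
fit_transition_moments <- function(datasets, system,
                                   grid = orientation_grid(20, 40)) {
  if (inherits(datasets, "vtvh_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, inherits(system, "spin_system"))
  pm <- profile_moments(datasets, system, grid)
  moments <- lapply(seq_along(datasets), function(k) {
    coef_to_moments(pm$coefficients[[k]], dataset_site(datasets[[k]]))
  })
  polar <- lapply(seq_along(moments), function(k) {
    m <- moments[[k]]
    if (sum(c(m$M_xy, m$M_xz, m$M_yz) != 0) < 2L) {
      c(x = NA_real_, y = NA_real_, z = NA_real_)
    } else {
      fractional_polarizations(m)
    }
  })
  structure(
    list(moments = moments, polarizations = polar, sse = pm$sse,
         degenerate = pm$degenerate, system = system,
         wavelengths = vapply(datasets, function(d) {
           as.numeric(attr(d, "wavelength_nm") %||% NA_real_)
         }, numeric(1))),
    class = "moment_fit"
  )
}

#' @export
print.moment_fit <- function(x, ...) {
  cat(sprintf("<moment_fit: %d band(s), SSE = %.6g>\n",
              length(x$moments), x$sse))
  for (k in seq_along(x$moments)) {
    m <- x$moments[[k]]
    p <- x$polarizations[[k]]
    cat(sprintf(
      "  %g nm: M_xy = %.4g, M_xz = %.4g, M_yz = %.4g (gamma %g)  %%pol (%.1f, %.1f, %.1f)%s\n",
      x$wavelengths[k], m$M_xy, m$M_xz, m$M_yz, m$gamma,
      p["x"], p["y"], p["z"],
      if (x$degenerate[k]) "  [degenerate]" else ""))
  }
  invisible(x)
}

#' Fit spin-Hamiltonian parameters (and moments) to VTVH data
#'
#' Joint refinement of selected spin-Hamiltonian parameters (D, E/D per
#' site, J) and the per-band transition moment products. The moments are
#' profiled out exactly (linear least squares) at every evaluation of the
#' nonlinear objective, so the outer problem runs only over the free
#' spin-Hamiltonian parameters, multi-started from a seeded Latin-hypercube
#' design over the bound box plus the starting system's own values.
#'
#' @param datasets a `vtvh_dataset` or list of them
#' @param system starting [spin_system()]; parameters not in `spec$free`
#'   stay clamped at the values stored here
#' @param spec a [fit_spec()] with at least one free parameter
#' @param grid an [orientation_grid()] (moderate density is adequate for
#'   fitting; simulate final curves at the default density)
#' @param control list passed to [stats::nlminb()]
#' @return An object of class `sh_fit`: best parameters, per-band moments at
#'   the optimum, weighted SSE, the per-restart table (distinct local minima
#'   are visible there), convergence flags and an under-determination flag.
#' @export
fit_spin_hamiltonian <- function(datasets, system, spec,
                                 grid = orientation_grid(20, 40),
                                 control = list(rel.tol = 1e-9)) {
  if (inherits(datasets, "vtvh_dataset")) datasets <- list(datasets)
  stopifnot(inherits(spec, "fit_spec"))
  if (!length(spec$free)) {
    stop("fit_spin_hamiltonian requires at least one free parameter; ",
         "use fit_transition_moments for a fixed system", call. = FALSE)
  }
  if (n_sites(system) == 1L &&
      length(setdiff(spec$free, c("D_1", "EoD_1")))) {
    stop("free parameters refer to a second site but the system has one",
         call. = FALSE)
  }
  n_pts <- sum(vapply(datasets, nrow, integer(1)))
  n_par <- length(spec$free) + 3L * length(datasets)
  underdetermined <- n_par >= n_pts
  if (underdetermined) {
    warning("fit is under-determined: ", n_par, " parameters for ",
            n_pts, " data points", call. = FALSE)
  }

  free <- spec$free
  lo <- spec$lower[free]; up <- spec$upper[free]
  objective <- function(p) {
    names(p) <- free
    sys2 <- apply_parameters(system, p)
    profile_moments(datasets, sys2, grid)$sse
  }

  # seeded multi-start: current system values + Latin hypercube over bounds
  starts <- matrix(system_parameters(system)[free], nrow = 1,
                   dimnames = list(NULL, free))
  starts[1, ] <- pmin(pmax(starts[1, ], lo), up)
  if (spec$n_starts > 1L) {
    u <- with_seed(spec$seed, lhs::randomLHS(spec$n_starts - 1L, length(free)))
    extra <- sweep(sweep(u, 2, up - lo, "*"), 2, lo, "+")
    colnames(extra) <- free
    starts <- rbind(starts, extra)
  }

  restarts <- vector("list", nrow(starts))
  for (r in seq_len(nrow(starts))) {
    opt <- stats::nlminb(starts[r, ], objective, lower = lo, upper = up,
                         control = control)
    restarts[[r]] <- data.frame(
      restart = r, t(setNames(opt$par, free)), sse = opt$objective,
      converged = opt$convergence == 0
    )
  }
  restart_df <- do.call(rbind, restarts)
  best <- which.min(restart_df$sse)
  best_par <- setNames(as.numeric(restart_df[best, free]), free)
  best_system <- apply_parameters(system, best_par)
  mom <- fit_transition_moments(datasets, best_system, grid = grid)

  structure(
    list(parameters = best_par, system = best_system,
         moments = mom$moments, polarizations = mom$polarizations,
         sse = restart_df$sse[best], restarts = restart_df,
         converged = restart_df$converged[best],
         underdetermined = underdetermined, spec = spec),
    class = "sh_fit"
  )
}

#' @export
print.sh_fit <- function(x, ...) {
  cat("<sh_fit>\n  parameters: ",
      paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
            collapse = ", "),
      sprintf("\n  SSE = %.6g over %d restart(s); best restart converged: %s\n",
              x$sse, nrow(x$restarts), x$converged))
  if (x$underdetermined) cat("  [flag] under-determined fit\n")
  invisible(x)
}

#' Scan the error surface of one spin-Hamiltonian parameter
#'
#' Profile-likelihood style uncertainty analysis: the named parameter is
#' clamped at each grid value and all remaining free parameters (plus the
#' per-band moments) are re-optimized, warm-starting each grid point from
#' its neighbour's optimum. Returns the SSE profile and the trajectories of
#' the co-fitted parameters, which is how flat directions (such as the
#' exchange constant J compensated by the ZFS of the weakly split site) are
#' diagnosed.
#'
#' @param datasets a `vtvh_dataset` or list of them
#' @param system starting [spin_system()]
#' @param spec a [fit_spec()]; `parameter` need not be listed free
#' @param parameter name of the parameter to scan
#' @param values grid of values (must lie within the spec bounds)
#' @param grid an [orientation_grid()]
#' @return An object of class `error_surface`: a data frame with the scanned
#'   value, re-optimized SSE and co-fitted parameter columns.
#' @export
scan_error_surface <- function(datasets, system, spec, parameter, values,
                               grid = orientation_grid(20, 40)) {
  if (inherits(datasets, "vtvh_dataset")) datasets <- list(datasets)
  stopifnot(parameter %in% .SH_PAR_NAMES, length(values) >= 1)
  if (any(values < spec$lower[parameter] - 1e-9) ||
      any(values > spec$upper[parameter] + 1e-9)) {
    stop("scan grid lies outside the parameter bounds", call. = FALSE)
  }
  co_free <- setdiff(spec$free, parameter)
  rows <- vector("list", length(values))
  sys_r <- system
  for (i in seq_along(values)) {
    sys_i <- apply_parameters(sys_r, setNames(values[i], parameter))
    if (length(co_free)) {
      spec_i <- fit_spec(free = co_free, lower = spec$lower[co_free],
                         upper = spec$upper[co_free],
                         n_starts = if (i == 1L) spec$n_starts else 1L,
                         seed = spec$seed)
      fit_i <- fit_spin_hamiltonian(datasets, sys_i, spec_i, grid = grid)
      sse_i <- fit_i$sse
      co <- fit_i$parameters
      sys_r <- fit_i$system   # warm start for the next grid point
    } else {
      sse_i <- profile_moments(datasets, sys_i, grid)$sse
      co <- numeric(0)
    }
    rows[[i]] <- data.frame(value = values[i], sse = sse_i,
                            t(as.data.frame(co)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[1] <- parameter
  structure(out, class = c("error_surface", "data.frame"),
            parameter = parameter, co_fitted = co_free)
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
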