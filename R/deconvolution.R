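#' An absorption or MCD spectrum
#'
#' @param energy strictly increasing energy grid, cm^-1
#' @param intensity epsilon (ABS) or delta-epsilon (MCD), consistent
#'   arbitrary units
#' @param kind `"abs"` or `"mcd"`
#' @param T,B measurement temperature (K) and field (T); meaningful for MCD
#' @return A data frame of class `spectrum` with columns `energy_cm1`,
#'   `intensity`; kind and conditions stored as attributes.
#' @export
spectrum <- function(energy, intensity, kind = c("abs", "mcd"),
                     T = NA_real_, B = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(energy) == length(intensity), length(energy) >= 2)
  if (!all(is.finite(energy)) || !all(is.finite(intensity))) {
    stop("non-finite values in spectrum", call. = FALSE)
  }
  if (anyDuplicated(energy)) {
    stop("duplicate energies in spectrum", call. = FALSE)
  }
  if (is.unsorted(energy)) {
    warning("energy grid not sorted; sorting", call. = FALSE)
    o <- order(energy)
    energy <- energy[o]; intensity <- intensity[o]
  }
  structure(data.frame(energy_cm1 = energy, intensity = intensity),
            class = c("spectrum", "data.frame"),
            kind = kind, T_K = T, B_T = B)
}

#' Gaussian band parameters
#'
#' A table of Gaussian bands shared between an absorption and an MCD
#' spectrum: common center (the MCD center may shift by at most a small
#' fraction of the center), full width at half maximum, a non-negative ABS
#' amplitude and a signed MCD amplitude.
#'
#' @param center band centers, cm^-1
#' @param fwhm full widths at half maximum, cm^-1 (> 0)
#' @param abs_amplitude ABS peak amplitudes (>= 0)
#' @param mcd_amplitude signed MCD peak amplitudes
#' @param mcd_center_shift fractional shift of the MCD center relative to
#'   `center` (|shift| <= 0.03 by convention)
#' @return A data frame of class `gaussian_bands`.
#' @examples
#' gaussian_bands(center = c(7280, 9700), fwhm = 2500,
#'                abs_amplitude = 1, mcd_amplitude = c(1, -1))
#' @export
gaussian_bands <- function(center, fwhm, abs_amplitude, mcd_amplitude,
                           mcd_center_shift = 0) {
  n <- length(center)
  df <- data.frame(
    center = center,
    fwhm = rep_len(fwhm, n),
    abs_amplitude = rep_len(abs_amplitude, n),
    mcd_amplitude = rep_len(mcd_amplitude, n),
    mcd_center_shift = rep_len(mcd_center_shift, n)
  )
  if (any(df$fwhm <= 0)) stop("fwhm must be > 0", call. = FALSE)
  if (any(df$abs_amplitude < 0)) {
    stop("ABS amplitudes must be >= 0", call. = FALSE)
  }
  if (any(abs(df$mcd_center_shift) > 0.03 + 1e-12)) {
    stop("|mcd_center_shift| must be <= 0.03", call. = FALSE)
  }
  structure(df, class = c("gaussian_bands", "data.frame"))
}

.FWHM2SD <- 1 / (2 * sqrt(2 * log(2)))

# model spectra from a band table
band_profile <- function(bands, energy, which = c("abs", "mcd")) {
  which <- match.arg(which)
  out <- numeric(length(energy))
  for (k in seq_len(nrow(bands))) {
    s <- bands$fwhm[k] * .FWHM2SD
    if (which == "abs") {
      out <- out + bands$abs_amplitude[k] *
        exp(-(energy - bands$center[k])^2 / (2 * s^2))
    } else {
      c_mcd <- bands$center[k] * (1 + bands$mcd_center_shift[k])
      out <- out + bands$mcd_amplitude[k] *
        exp(-(energy - c_mcd)^2 / (2 * s^2))
    }
  }
  out
}

#' Simultaneous Gaussian deconvolution of paired ABS and MCD spectra
#'
#' Least-squares fit of `n_bands` Gaussians to an absorption and an MCD
#' spectrum jointly. Band centers are shared between the two spectra up to a
#' hard fractional bound (`shift_bound`, default 3%); widths are per band
#' and shared between the two spectra; ABS amplitudes are constrained
#' non-negative while MCD amplitudes carry a sign. Each spectrum's residual
#' is scaled by its maximum absolute intensity so neither dominates by
#' units. Optimization uses Levenberg-Marquardt with box constraints
#' ([minpack.lm::nls.lm]).
#'
#' @param abs_spec,mcd_spec [spectrum()] objects with overlapping ranges
#' @param init a [gaussian_bands()] table of initial guesses (its row count
#'   sets `n_bands`)
#' @param shift_bound maximum |MCD center - ABS center| / center
#' @param center_window centers are constrained within +/- this many cm^-1
#'   of their initial guesses (keeps band identities during refinement)
#' @param fwhm_bounds length-2 vector bounding all widths, cm^-1
#' @param max_iter maximum Levenberg-Marquardt iterations
#' @return An object of class `deconvolution`: the refined
#'   [gaussian_bands()] table (sorted by center), per-spectrum residual
#'   norms, and the inputs needed to reconstruct the fit.
#' @export
simultaneous_deconvolve <- function(abs_spec, mcd_spec, init,
                                    shift_bound = 0.03,
                                    center_window = 1500,
                                    fwhm_bounds = c(500, 8000),
                                    max_iter = 400) {
  stopifnot(inherits(abs_spec, "spectrum"), inherits(mcd_spec, "spectrum"))
  stopifnot(identical(attr(abs_spec, "kind"), "abs"),
            identical(attr(mcd_spec, "kind"), "mcd"))
  if (!inherits(init, "gaussian_bands")) {
    stop("init must be a gaussian_bands table", call. = FALSE)
  }
  n_bands <- nrow(init)
  lo_e <- max(min(abs_spec$energy_cm1), min(mcd_spec$energy_cm1))
  hi_e <- min(max(abs_spec$energy_cm1), max(mcd_spec$energy_cm1))
  if (hi_e <= lo_e) {
    stop("ABS and MCD spectra do not overlap in energy", call. = FALSE)
  }
  n_pts <- nrow(abs_spec) + nrow(mcd_spec)
  if (5 * n_bands > n_pts) {
    stop("too many bands (", n_bands, ") for ", n_pts,
         " spectral points; fit not identifiable", call. = FALSE)
  }

  # Spectra and amplitudes are fitted in units of each spectrum's maximum
  # absolute intensity: residuals are balanced between the two spectra and
  # the optimization path is exactly invariant under a common rescaling of
  # the input data.
  s_abs <- max(abs(abs_spec$intensity))
  s_mcd <- max(abs(mcd_spec$intensity))
  if (s_abs == 0 || s_mcd == 0) {
    stop("a spectrum with all-zero intensities cannot be deconvolved",
         call. = FALSE)
  }
  y_abs <- abs_spec$intensity / s_abs
  y_mcd <- mcd_spec$intensity / s_mcd

  # parameter packing: center_k, fwhm_k, abs_amp_k, mcd_amp_k, shift_k
  # (amplitudes in normalized units)
  pack <- function(b) {
    c(b$center, b$fwhm, b$abs_amplitude / s_abs, b$mcd_amplitude / s_mcd,
      b$mcd_center_shift)
  }
  unpack <- function(p) {
    k <- n_bands
    data.frame(center = p[1:k], fwhm = p[k + 1:k],
               abs_amplitude = p[2 * k + 1:k],
               mcd_amplitude = p[3 * k + 1:k],
               mcd_center_shift = p[4 * k + 1:k])
  }
  resid_fn <- function(p) {
    b <- unpack(p)
    c(band_profile(b, abs_spec$energy_cm1, "abs") - y_abs,
      band_profile(b, mcd_spec$energy_cm1, "mcd") - y_mcd)
  }
  lower <- c(init$center - center_window, rep(fwhm_bounds[1], n_bands),
             rep(0, n_bands), rep(-Inf, n_bands),
             rep(-shift_bound, n_bands))
  upper <- c(init$center + center_window, rep(fwhm_bounds[2], n_bands),
             rep(Inf, n_bands), rep(Inf, n_bands),
             rep(shift_bound, n_bands))
  p0 <- pmin(pmax(pack(init), lower), upper)

  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         maxfev = 100000)
  )
  b <- unpack(fit$par)
  o <- order(b$center)
  b <- b[o, , drop = FALSE]
  rownames(b) <- NULL
  bands <- gaussian_bands(b$center, b$fwhm, b$abs_amplitude * s_abs,
                          b$mcd_amplitude * s_mcd, b$mcd_center_shift)
  r_abs <- band_profile(bands, abs_spec$energy_cm1, "abs") -
    abs_spec$intensity
  r_mcd <- band_profile(bands, mcd_spec$energy_cm1, "mcd") -
    mcd_spec$intensity
  structure(
    list(bands = bands,
         residual_norms = c(abs = sqrt(sum(r_abs^2)),
                            mcd = sqrt(sum(r_mcd^2))),
         sse = fit$deviance, niter = fit$niter,
         converged = fit$info %in% 1:4,
         abs_spec = abs_spec, mcd_spec = mcd_spec),
    class = "deconvolution"
  )
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("<deconvolution: %d bands, residual norms abs %.4g / mcd %.4g>\n",
              nrow(x$bands), x$residual_norms["abs"],
              x$residual_norms["mcd"]))
  print(cbind(round(x$bands, 3)), ...)
  invisible(x)
}

#' Initial band guesses for a simultaneous deconvolution
#'
#' Builds a [gaussian_bands()] initial-guess table from candidate centers:
#' amplitudes are read off the two spectra at each center (the usual manual
#' starting point), widths start at a common value.
#'
#' @param abs_spec,mcd_spec [spectrum()] objects
#' @param centers candidate band centers, cm^-1
#' @param fwhm starting width, cm^-1
#' @return A [gaussian_bands()] table.
#' @export
deconvolution_init <- function(abs_spec, mcd_spec, centers, fwhm = 2500) {
  a0 <- stats::approx(abs_spec$energy_cm1, abs_spec$intensity, centers,
                      rule = 2)$y
  m0 <- stats::approx(mcd_spec$energy_cm1, mcd_spec$intensity, centers,
                      rule = 2)$y
  gaussian_bands(centers, fwhm, abs_amplitude = pmax(a0, 0),
                 mcd_amplitude = m0)
}

#' C0/D0 ratio of a Gaussian band
#'
#' Moment-analysis ratio of the MCD C-term zeroth moment to the dipole
#' strength of the same band,
#' C0/D0 = (kT / beta B) * \[integral of (delta-eps / E) dE\] /
#' \[integral of (eps / E) dE\], the integrals running over the band's
#' Gaussian profiles. The sign follows the MCD band sign; at fixed
#' amplitudes the ratio is linear in T and inversely proportional to B.
#' Large |C0/D0| marks metal-centered (d-d) transitions, which borrow
#' spin-orbit intensity efficiently; CT bands give small ratios.
#'
#' @param band one row of a [gaussian_bands()] table (or the whole table)
#' @param T temperature, K (> 0)
#' @param B field, Tesla (> 0)
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' b <- gaussian_bands(9700, 2500, 1, -1)
#' c0_over_d0(b, T = 5, B = 7)
#' @export
c0_over_d0 <- function(band, T, B) {
  stopifnot(is.data.frame(band), nrow(band) >= 1)
  if (T <= 0 || B <= 0) stop("need T > 0 and B > 0", call. = FALSE)
  vapply(seq_len(nrow(band)), function(k) {
    bk <- band[k, ]
    if (bk$abs_amplitude == 0) {
      stop("zero ABS amplitude: dipole strength vanishes", call. = FALSE)
    }
    if (bk$mcd_amplitude == 0) return(0)
    s <- bk$fwhm * .FWHM2SD
    gauss_over_E <- function(center) {
      lo <- max(center - 8 * s, 1)
      stats::integrate(function(E) {
        exp(-(E - center)^2 / (2 * s^2)) / E
      }, lower = lo, upper = center + 8 * s, rel.tol = 1e-10)$value
    }
    m_mcd <- bk$mcd_amplitude *
      gauss_over_E(bk$center * (1 + bk$mcd_center_shift))
    m_abs <- bk$abs_amplitude * gauss_over_E(bk$center)
    (.KB_CM1_K * T / (.BETA_CM1_T * B)) * m_mcd / m_abs
  }, numeric(1))
}

#' Classify bands as d-d or charge transfer from C0/D0
#'
#' Bands with |C0/D0| strictly above the threshold (default 0.17) are
#' classified as metal-centered d-d transitions; the rest as charge transfer
#' (CT). A ratio exactly at the threshold is CT (strict inequality).
#' The classification is invariant under any common rescaling of the two
#' spectra, since C0/D0 is a ratio of band moments.
#'
#' @param ratio numeric C0/D0 values (as from [c0_over_d0()])
#' @param threshold classification threshold on |C0/D0|
#' @return Character vector, `"d-d"` or `"CT"`.
#' @examples
#' classify_band(c(-0.95, 0.05, 0.17))   # "d-d" "CT" "CT"
#' @export
classify_band <- function(ratio, threshold = 0.17) {
  stopifnot(is.numeric(ratio), threshold >= 0)
  ifelse(abs(ratio) > threshold, "d-d", "CT")
}
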