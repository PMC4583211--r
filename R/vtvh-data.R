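#' A VTVH MCD dataset at one wavelength
#'
#' Measured or simulated MCD intensity as a function of field and
#' temperature at a fixed detection wavelength.
#'
#' @param wavelength_nm detection wavelength, nm
#' @param B fields, Tesla (>= 0)
#' @param T temperatures, Kelvin (> 0)
#' @param intensity intensities (arbitrary units)
#' @param sigma optional per-point uncertainties (> 0); absent means unit
#'   weights in fitting
#' @param site which site's spin operators the band couples to (`"total"`,
#'   `"A"`, `"B"`); only meaningful for dimers
#' @param truth optional list of generating parameters (attached by the
#'   synthetic-data generators for recovery scoring)
#' @return A data frame of class `vtvh_dataset` with columns `B_T`, `T_K`,
#'   `intensity` and optionally `sigma`; wavelength, site and truth are
#'   attributes.
#' @export
vtvh_dataset <- function(wavelength_nm, B, T, intensity, sigma = NULL,
                         site = c("total", "A", "B"), truth = NULL) {
  site <- match.arg(site)
  n <- length(B)
  stopifnot(length(T) == n, length(intensity) == n)
  if (any(B < 0)) stop("fields must be >= 0", call. = FALSE)
  if (any(T <= 0)) stop("temperatures must be > 0", call. = FALSE)
  if (!all(is.finite(intensity))) {
    stop("non-finite intensities in dataset", call. = FALSE)
  }
  df <- data.frame(B_T = B, T_K = T, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == n, all(sigma > 0))
    df$sigma <- sigma
  }
  structure(df, class = c("vtvh_dataset", "data.frame"),
            wavelength_nm = wavelength_nm, site = site, truth = truth)
}

dataset_site <- function(d) attr(d, "site") %||% "total"
dataset_weights <- function(d) {
  if ("sigma" %in% names(d)) 1 / d$sigma^2 else rep(1, nrow(d))
}

#' @export
print.vtvh_dataset <- function(x, ...) {
  cat(sprintf("<vtvh_dataset: %g nm, %d points, %d field(s) x %d temperature(s), site %s>\n",
              attr(x, "wavelength_nm"), nrow(x),
              length(unique(x$B_T)), length(unique(x$T_K)), dataset_site(x)))
  invisible(x)
}
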