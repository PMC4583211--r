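# CSV input/output for VTVH datasets and spectra. Columns and units:
#   VTVH:     wavelength_nm, B_T, T_K, intensity [, sigma]
#   spectrum: energy_cm1, intensity
# Energies are cm^-1 everywhere; wavelengths nm; fields Tesla; temperatures
# Kelvin.

#' Read and write VTVH MCD data as CSV
#'
#' The file holds one row per (wavelength, field, temperature) point with
#' columns `wavelength_nm`, `B_T`, `T_K`, `intensity` and optionally
#' `sigma`. Reading splits the table into one [vtvh_dataset()] per
#' wavelength; rows with non-positive temperature or negative field are
#' rejected with their row numbers. When `sigma` is absent unit weights are
#' recorded.
#'
#' @param path CSV file path
#' @return `read_vtvh()`: a list of [vtvh_dataset()] objects.
#' @export
read_vtvh <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "B_T", "T_K", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_sigma <- "sigma" %in% names(df)
  cols <- c(need, if (has_sigma) "sigma")
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))
        stop("non-numeric values in column '", cl, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      df[[cl]] <- vn
    }
  }
  if (anyNA(df[cols])) {
    bad <- which(rowSums(is.na(df[cols])) > 0)
    stop("missing/non-numeric cells at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_T <- which(df$T_K <= 0)
  if (length(bad_T)) {
    stop("non-positive temperature at row(s) ",
         paste(utils::head(bad_T, 5), collapse = ", "), call. = FALSE)
  }
  bad_B <- which(df$B_T < 0)
  if (length(bad_B)) {
    stop("negative field at row(s) ",
         paste(utils::head(bad_B, 5), collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$wavelength_nm), function(d) {
    vtvh_dataset(d$wavelength_nm[1], d$B_T, d$T_K, d$intensity,
                 sigma = if (has_sigma) d$sigma)
  })
}

#' @rdname read_vtvh
#' @param datasets a [vtvh_dataset()] or list of them
#' @export
write_vtvh <- function(datasets, path) {
  if (inherits(datasets, "vtvh_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    out <- data.frame(wavelength_nm = attr(d, "wavelength_nm"),
                      B_T = d$B_T, T_K = d$T_K, intensity = d$intensity)
    if ("sigma" %in% names(d)) out$sigma <- d$sigma
    out
  })
  # a mixture of with/without sigma is written without the column
  if (length(unique(vapply(rows, ncol, integer(1)))) > 1L) {
    rows <- lapply(rows, function(r) r[c("wavelength_nm", "B_T", "T_K",
                                         "intensity")])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write a spectrum as CSV
#'
#' Columns `energy_cm1`, `intensity`. An unsorted grid is sorted with a
#' warning; duplicate energies are an error.
#'
#' @param path CSV file path
#' @param kind `"abs"` or `"mcd"`
#' @return `read_spectrum()`: a [spectrum()] object.
#' @export
read_spectrum <- function(path, kind = c("abs", "mcd")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("energy_cm1", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty spectrum file: ", path, call. = FALSE)
  spectrum(df$energy_cm1, df$intensity, kind = kind)
}

#' @rdname read_spectrum
#' @param spec a [spectrum()] object
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(data.frame(energy_cm1 = spec$energy_cm1,
                              intensity = spec$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write VTVH curves as CSV
#'
#' Columns `B_T`, `T_K`, `beta_B_over_kT`, `intensity`.
#'
#' @param curves a `vtvh_curves` data frame from [vtvh_curves()]
#' @param path CSV file path
#' @export
write_vtvh_curves <- function(curves, path) {
  stopifnot(is.data.frame(curves))
  utils::write.csv(curves[c("B_T", "T_K", "beta_B_over_kT", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}
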