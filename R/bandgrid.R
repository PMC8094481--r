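#' Sensor band grids
#'
#' A `band_grid` describes an imaging spectrometer's sampling: the centre
#' wavelength of band 1, the (uniform) sampling step, the number of bands and
#' the spectral resolution (full width at half maximum of the spectral
#' response function). Band indexing is 1-based everywhere: band `k` is
#' centred at `start_nm + step_nm * (k - 1)`.
#'
#' @param start_nm Centre wavelength of band 1, in nm.
#' @param step_nm Sampling interval in nm; must be positive.
#' @param n_bands Number of bands; at least 2.
#' @param fwhm_nm Spectral resolution (FWHM of the SRF) in nm.
#' @return An object of class `band_grid`.
#' @examples
#' g <- uhd_grid()
#' band_wavelength(g, 3)   # 458
#' band_wavelength(g, 96)  # 830
#' @export
band_grid <- function(start_nm, step_nm, n_bands, fwhm_nm) {
  stopifnot_scalar_number(start_nm, "start_nm")
  stopifnot_scalar_number(step_nm, "step_nm")
  stopifnot_scalar_number(fwhm_nm, "fwhm_nm")
  if (step_nm <= 0) stop("`step_nm` must be > 0", call. = FALSE)
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2L) stop("`n_bands` must be >= 2", call. = FALSE)
  if (fwhm_nm <= 0) stop("`fwhm_nm` must be > 0", call. = FALSE)
  structure(
    list(start_nm = start_nm, step_nm = step_nm,
         n_bands = n_bands, fwhm_nm = fwhm_nm),
    class = "band_grid"
  )
}

#' @describeIn band_grid The UHD185-style imaging grid: 125 bands, 4 nm
#'   sampling from 450 nm, 8 nm resolution. Band 3 sits at 458 nm and band 96
#'   at 830 nm, the limits of the sensor's reliable range.
#' @export
uhd_grid <- function() band_grid(450, 4, 125, 8)

#' @describeIn band_grid A fine field-spectroradiometer style grid used as the
#'   ASD-like reference in cross-sensor checks: 1 nm sampling, 3 nm
#'   resolution, covering `from`--`to` nm (default 400--1000).
#' @param from,to Wavelength window for `asd_grid()`, in nm.
#' @export
asd_grid <- function(from = 400, to = 1000) {
  band_grid(from, 1, as.integer(to - from + 1), 3)
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("<band_grid> %d bands, %g-%g nm (step %g nm, FWHM %g nm)\n",
              x$n_bands, x$start_nm, band_wavelength(x, x$n_bands),
              x$step_nm, x$fwhm_nm))
  invisible(x)
}

#' Band index to wavelength and back
#'
#' @param grid A [band_grid()].
#' @param k Band index (1-based); may be a vector.
#' @return `band_wavelength()` returns centre wavelengths in nm;
#'   `wavelength_band()` returns the 1-based band index whose centre equals
#'   the given wavelength.
#' @export
band_wavelength <- function(grid, k) {
  stopifnot(inherits(grid, "band_grid"))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > grid$n_bands)) {
    stop(sprintf("band index out of range 1..%d", grid$n_bands), call. = FALSE)
  }
  grid$start_nm + grid$step_nm * (k - 1)
}

#' @rdname band_wavelength
#' @param nm Wavelength(s) in nm; must coincide with a band centre.
#' @export
wavelength_band <- function(grid, nm) {
  stopifnot(inherits(grid, "band_grid"))
  k <- (nm - grid$start_nm) / grid$step_nm + 1
  ki <- as.integer(round(k))
  if (any(abs(k - ki) > 1e-8) || any(ki < 1L) || any(ki > grid$n_bands)) {
    stop("wavelength does not coincide with a band centre on this grid",
         call. = FALSE)
  }
  ki
}

#' @rdname band_wavelength
#' @export
grid_wavelengths <- function(grid) {
  band_wavelength(grid, seq_len(grid$n_bands))
}
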