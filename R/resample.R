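#' Fine-grid spectrum
#'
#' A `fine_spectrum` is a reflectance curve on a strictly increasing
#' wavelength grid (nominally 1 nm over at least 400--1000 nm), standing in
#' for a field spectroradiometer measurement.
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param reflectance Reflectance in \[0, 1\], same length.
#' @return An object of class `fine_spectrum`.
#' @export
fine_spectrum <- function(wavelengths, reflectance) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have the same length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(reflectance < -1e-9 | reflectance > 1 + 1e-9)) {
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths,
                 reflectance = pmin(pmax(reflectance, 0), 1)),
            class = "fine_spectrum")
}

# SRF weights of one band over the fine wavelengths; support +/- 2 FWHM.
srf_weights <- function(fine_wl, center, fwhm, shape = c("gaussian", "boxcar")) {
  shape <- match.arg(shape)
  half <- 2 * fwhm
  in_support <- fine_wl >= center - half & fine_wl <= center + half
  w <- numeric(length(fine_wl))
  if (shape == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    w[in_support] <- exp(-((fine_wl[in_support] - center)^2) / (2 * sigma^2))
  } else {
    # boxcar: interval average over +/- FWHM/2
    box <- fine_wl >= center - fwhm / 2 & fine_wl <= center + fwhm / 2
    w[box] <- 1
  }
  w / sum(w)
}

#' Resample a fine spectrum onto a sensor band grid
#'
#' Each band value is the spectral-response-function weighted average of the
#' fine reflectance: a Gaussian SRF centred at the band centre with
#' FWHM = `grid$fwhm_nm`, truncated at +/- 2 FWHM and normalised to unit sum
#' (a boxcar interval average over one FWHM is available as an alternative).
#' The fine grid must cover the full truncated support of every band.
#'
#' @param fine A [fine_spectrum()].
#' @param grid Target [band_grid()].
#' @param srf SRF shape, `"gaussian"` (default) or `"boxcar"`.
#' @return Numeric vector of band reflectances, length `grid$n_bands`, named
#'   by wavelength.
#' @export
resample_to_grid <- function(fine, grid, srf = c("gaussian", "boxcar")) {
  stopifnot(inherits(fine, "fine_spectrum"), inherits(grid, "band_grid"))
  srf <- match.arg(srf)
  centers <- grid_wavelengths(grid)
  half <- 2 * grid$fwhm_nm
  lo <- min(fine$wavelengths); hi <- max(fine$wavelengths)
  bad <- which(centers - half < lo - 1e-9 | centers + half > hi + 1e-9)
  if (length(bad)) {
    stop(sprintf(
      "fine grid [%g, %g] nm does not cover band %d (centre %g nm, needs [%g, %g])",
      lo, hi, bad[1], centers[bad[1]],
      centers[bad[1]] - half, centers[bad[1]] + half), call. = FALSE)
  }
  out <- vapply(centers, function(cw) {
    w <- srf_weights(fine$wavelengths, cw, grid$fwhm_nm, srf)
    sum(w * fine$reflectance)
  }, numeric(1))
  names(out) <- paste0("w", centers)
  out
}

#' Resample many fine spectra into a spectra set
#'
#' @param fines List of [fine_spectrum()] objects, one per sample.
#' @param grid Target [band_grid()].
#' @param metadata,lai Passed through to [spectra_set()].
#' @param srf SRF shape, see [resample_to_grid()].
#' @param noise_sd Additive Gaussian measurement noise (reflectance units)
#'   applied per band after resampling; 0 disables. Clipped to \[0, 1\].
#' @param seed RNG seed for the noise.
#' @return A [spectra_set()] on `grid`.
#' @export
resample_set <- function(fines, grid, metadata = NULL, lai = NULL,
                         srf = "gaussian", noise_sd = 0, seed = NULL) {
  refl <- t(vapply(fines, resample_to_grid, numeric(grid$n_bands),
                   grid = grid, srf = srf))
  if (noise_sd > 0) {
    refl <- with_seed(seed, refl + stats::rnorm(length(refl), 0, noise_sd))
    refl <- pmin(pmax(refl, 0), 1)
  }
  spectra_set(refl, grid, metadata, lai)
}
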