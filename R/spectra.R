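#' Spectra set container
#'
#' A `spectra_set` couples a reflectance matrix (rows = plot-stage samples,
#' columns = sensor bands) with its [band_grid()], per-sample metadata and an
#' optional measured-LAI vector. Column count must equal the grid's band
#' count; metadata and LAI are row-aligned.
#'
#' @param reflectance Numeric matrix, samples x bands, values in \[0, 1\].
#' @param grid A [band_grid()] with `n_bands == ncol(reflectance)`.
#' @param metadata A data.frame with one row per sample. Conventionally holds
#'   `sample_id`, `plot_id`, `stage`, `cultivar`, `n_treatment`, `area`.
#' @param lai Optional numeric vector of measured LAI, one per row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(reflectance, grid, metadata = NULL, lai = NULL) {
  stopifnot(inherits(grid, "band_grid"))
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != grid$n_bands) {
    stop(sprintf("reflectance has %d columns but grid declares %d bands",
                 ncol(reflectance), grid$n_bands), call. = FALSE)
  }
  n <- nrow(reflectance)
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = as.character(seq_len(n)))
  }
  if (nrow(metadata) != n) {
    stop("metadata rows must align with reflectance rows", call. = FALSE)
  }
  if (!is.null(lai)) {
    lai <- as.numeric(lai)
    if (length(lai) != n) stop("lai must align with reflectance rows", call. = FALSE)
  }
  colnames(reflectance) <- paste0("w", grid_wavelengths(grid))
  structure(list(reflectance = reflectance, grid = grid,
                 metadata = metadata, lai = lai),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%g-%g nm)%s\n",
              nrow(x$reflectance), x$grid$n_bands, x$grid$start_nm,
              band_wavelength(x$grid, x$grid$n_bands),
              if (is.null(x$lai)) "" else ", with LAI"))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by sample
#'
#' @param x A [spectra_set()].
#' @param i Row (sample) selector.
#' @return A `spectra_set` with the selected samples; metadata and LAI stay
#'   aligned.
#' @export
subset_samples <- function(x, i) {
  stopifnot(inherits(x, "spectra_set"))
  spectra_set(x$reflectance[i, , drop = FALSE], x$grid,
              x$metadata[i, , drop = FALSE],
              if (is.null(x$lai)) NULL else x$lai[i])
}

#' Trim a spectra set to its reliable band range
#'
#' Imaging-spectrometer edges are noisy; for the UHD185-style grid the
#' reliable range is bands 3--96, i.e. 458--830 nm, leaving 94 variables.
#' Returns a new `spectra_set` whose grid starts at band `k_lo`'s wavelength
#' with `k_hi - k_lo + 1` bands; row order, metadata and LAI alignment are
#' preserved.
#'
#' @param spectra A [spectra_set()].
#' @param k_lo,k_hi 1-based band range to keep (defaults 3 and 96).
#' @return A trimmed `spectra_set`.
#' @export
trim_reliable <- function(spectra, k_lo = 3L, k_hi = 96L) {
  stopifnot(inherits(spectra, "spectra_set"))
  g <- spectra$grid
  k_lo <- as.integer(k_lo); k_hi <- as.integer(k_hi)
  if (k_lo < 1L || k_hi > g$n_bands || k_lo > k_hi) {
    stop(sprintf("invalid band range [%d, %d] for a %d-band grid",
                 k_lo, k_hi, g$n_bands), call. = FALSE)
  }
  new_grid <- band_grid(band_wavelength(g, k_lo), g$step_nm,
                        max(k_hi - k_lo + 1L, 2L), g$fwhm_nm)
  if (k_hi == k_lo) {
    # degenerate single-band request: band_grid requires >= 2 bands, so carry
    # a 1-column matrix with a minimal 2-band grid truncated on output
    out <- spectra_set(cbind(spectra$reflectance[, k_lo, drop = FALSE],
                             spectra$reflectance[, k_lo, drop = FALSE]),
                       new_grid, spectra$metadata, spectra$lai)
    out$reflectance <- out$reflectance[, 1L, drop = FALSE]
    out$grid$n_bands <- 1L
    return(out)
  }
  spectra_set(spectra$reflectance[, k_lo:k_hi, drop = FALSE],
              new_grid, spectra$metadata, spectra$lai)
}

#' Cross-sensor consistency
#'
#' Squared Pearson correlation between two row/column-aligned spectra sets,
#' pooled over all (sample, band) reflectance pairs. Used to verify that an
#' imaging sensor agrees with a resampled field spectroradiometer
#' (agreement above 0.99 over the reliable range is the working criterion).
#'
#' @param a,b Two [spectra_set()] objects on the same grid with the same
#'   sample alignment.
#' @return The pooled coefficient of determination in \[0, 1\].
#' @export
cross_sensor_r2 <- function(a, b) {
  stopifnot(inherits(a, "spectra_set"), inherits(b, "spectra_set"))
  if (!identical(dim(a$reflectance), dim(b$reflectance))) {
    stop("spectra sets are not aligned: dimensions differ", call. = FALSE)
  }
  if (abs(a$grid$start_nm - b$grid$start_nm) > 1e-9 ||
      abs(a$grid$step_nm - b$grid$step_nm) > 1e-9) {
    stop("spectra sets are not on the same band grid", call. = FALSE)
  }
  stats::cor(as.vector(a$reflectance), as.vector(b$reflectance))^2
}
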