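#' First-derivative transform of a spectra set
#'
#' Central-difference derivative with respect to wavelength,
#' `FD_k = (R_{k+1} - R_{k-1}) / (lambda_{k+1} - lambda_{k-1})`, computed for
#' interior bands; the two edge bands are dropped. A forward-difference
#' stencil (`(R_{k+1} - R_k) / step`, dropping the last band) is available.
#' The derivative removes linear and near-linear background signal and
#' sharpens features such as the red edge. Units are 1/nm, so values are no
#' longer constrained to \[0, 1\]; the result is returned as a plain list
#' rather than a `spectra_set`.
#'
#' @param spectra A [spectra_set()] with at least 3 bands on a uniform grid.
#' @param stencil `"central"` (default) or `"forward"`.
#' @return A list with `values` (matrix, samples x derivative bands),
#'   `wavelengths` (nm of retained bands), `metadata`, `lai`.
#' @export
first_derivative <- function(spectra, stencil = c("central", "forward")) {
  stopifnot(inherits(spectra, "spectra_set"))
  stencil <- match.arg(stencil)
  R <- spectra$reflectance
  p <- ncol(R)
  if (p < 3L) stop("need at least 3 bands for a derivative", call. = FALSE)
  wl <- grid_wavelengths(spectra$grid)
  if (stencil == "central") {
    vals <- (R[, 3:p, drop = FALSE] - R[, 1:(p - 2), drop = FALSE]) /
      rep(wl[3:p] - wl[1:(p - 2)], each = nrow(R))
    keep <- 2:(p - 1)
  } else {
    vals <- (R[, 2:p, drop = FALSE] - R[, 1:(p - 1), drop = FALSE]) /
      rep(wl[2:p] - wl[1:(p - 1)], each = nrow(R))
    keep <- 1:(p - 1)
  }
  colnames(vals) <- paste0("d", wl[keep])
  list(values = vals, wavelengths = wl[keep],
       metadata = spectra$metadata, lai = spectra$lai)
}

#' Per-band Pearson correlation against LAI
#'
#' @param x A [spectra_set()] or the output of [first_derivative()].
#' @param lai Measured LAI vector; defaults to the one carried by `x`.
#' @return An object of class `correlation_spectrum`: a data.frame with
#'   columns `wavelength`, `r`, plus attributes `source` (`"raw"` or `"fd"`)
#'   and `zero_variance` (indices of constant bands, whose r is recorded
#'   as 0 with a warning).
#' @export
correlation_spectrum <- function(x, lai = NULL) {
  if (inherits(x, "spectra_set")) {
    vals <- x$reflectance
    wl <- grid_wavelengths(x$grid)
    src <- "raw"
    if (is.null(lai)) lai <- x$lai
  } else {
    vals <- x$values
    wl <- x$wavelengths
    src <- "fd"
    if (is.null(lai)) lai <- x$lai
  }
  if (is.null(lai)) stop("no LAI available", call. = FALSE)
  if (nrow(vals) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(lai) <= 0) stop("LAI has zero variance", call. = FALSE)
  sds <- apply(vals, 2, stats::sd)
  zero_var <- which(sds == 0)
  r <- rep(0, ncol(vals))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(vals[, ok, drop = FALSE], lai))
  if (length(zero_var)) {
    warning(sprintf("%d zero-variance band(s); correlation recorded as 0",
                    length(zero_var)), call. = FALSE)
  }
  out <- data.frame(wavelength = wl, r = r)
  attr(out, "source") <- src
  attr(out, "zero_variance") <- zero_var
  class(out) <- c("correlation_spectrum", "data.frame")
  out
}

#' Characteristic-band picking from an FD correlation spectrum
#'
#' Bands whose absolute correlation with LAI meets the threshold are grouped
#' into maximal runs of consecutive band indices; each run contributes its
#' band of maximal absolute correlation (ties broken toward the lower
#' wavelength). On real wheat spectra this reproduces picks such as 506, 546,
#' 774 and 830 nm from runs at 498--506, 542--546, 738--786 and 830 nm.
#'
#' @param corr A [correlation_spectrum()] (intended for FD-derived spectra).
#' @param threshold Absolute-correlation cut-off (default 0.6).
#' @return Integer vector of selected positions into `corr` (1-based), with
#'   the selected wavelengths as names. Empty if no band passes.
#' @export
fd_select_bands <- function(corr, threshold = 0.6) {
  stopifnot(inherits(corr, "correlation_spectrum"))
  pass <- which(abs(corr$r) >= threshold)
  if (!length(pass)) return(integer(0))
  run_id <- cumsum(c(1L, diff(pass) != 1L))
  picks <- vapply(split(pass, run_id), function(run) {
    run[which.max(abs(corr$r[run]))]   # which.max returns the first maximum
  }, integer(1))
  picks <- unname(picks)
  names(picks) <- corr$wavelength[picks]
  picks
}
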