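#' Read and write spectra tables
#'
#' The on-disk format is a plain CSV with one row per sample: `sample_id`,
#' `plot_id`, `stage`, `cultivar`, `n_treatment`, `area`, `lai`, then one
#' column per band named `w<nm>`. A JSON sidecar (`<path>.grid.json`)
#' records the band grid (`start_nm`, `step_nm`, `n_bands`, `fwhm_nm`), so a
#' written set round-trips exactly.
#'
#' @param spectra A [spectra_set()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_spectra_csv` returns a [spectra_set()].
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  meta <- spectra$metadata
  df <- cbind(meta,
              if (!is.null(spectra$lai)) data.frame(lai = spectra$lai),
              as.data.frame(spectra$reflectance))
  utils::write.csv(df, path, row.names = FALSE)
  g <- spectra$grid
  jsonlite::write_json(list(start_nm = g$start_nm, step_nm = g$step_nm,
                            n_bands = g$n_bands, fwhm_nm = g$fwhm_nm),
                       paste0(path, ".grid.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  gpath <- paste0(path, ".grid.json")
  band_cols <- grepl("^w[0-9.]+$", names(df))
  refl <- as.matrix(df[, band_cols, drop = FALSE])
  if (file.exists(gpath)) {
    g <- jsonlite::read_json(gpath, simplifyVector = TRUE)
    grid <- band_grid(g$start_nm, g$step_nm, g$n_bands, g$fwhm_nm)
  } else {
    wl <- as.numeric(sub("^w", "", names(df)[band_cols]))
    grid <- band_grid(wl[1], diff(wl)[1], length(wl), diff(wl)[1] * 2)
  }
  lai <- if ("lai" %in% names(df)) df$lai else NULL
  meta <- df[, !band_cols & names(df) != "lai", drop = FALSE]
  spectra_set(refl, grid, metadata = meta, lai = lai)
}

#' Serialise a selection result
#'
#' JSON carries the method, indices, wavelengths and score; the trace is
#' written as a separate CSV table when it is tabular.
#'
#' @param sel A `selection_result`.
#' @param path Output JSON path; the trace CSV goes to `<path>.trace.csv`.
#' @export
write_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(list(method = sel$method,
                            selected_indices = sel$selected_indices,
                            selected_wavelengths = sel$selected_wavelengths,
                            score = sel$score),
                       path, auto_unbox = TRUE, digits = NA)
  tr <- sel$trace
  if (is.data.frame(tr)) {
    utils::write.csv(tr, paste0(path, ".trace.csv"), row.names = FALSE)
  } else if (is.list(tr) && is.data.frame(tr$cars)) {
    utils::write.csv(tr$cars, paste0(path, ".trace.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML when the `yaml` package is available and the file extension is
#' `.yml`/`.yaml`, otherwise JSON. Either format maps to the nested named
#' list that [run_pipeline()] accepts.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the `yaml` package; use JSON instead",
           call. = FALSE)
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config Named list to archive.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE) &&
      requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
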