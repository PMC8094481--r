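#' Run the end-to-end LAI estimation pipeline
#'
#' Generates (or loads) a spectra table, trims to the reliable band range,
#' runs the requested selectors and models through [run_comparison()], and
#' writes all artifacts — comparison table, selection traces, fitted models,
#' calibration/validation scatter data, the archived config and a run log —
#' into the output directory. Partial failures are isolated per row; the
#' call errors only if no row completes.
#'
#' @param config Named list (or path to a YAML/JSON file readable by
#'   [read_config()]). Recognised top-level keys: `seed`, `out_dir`,
#'   `input_csv` (load instead of simulate), `n_plots`, `trim` (list
#'   `k_lo`, `k_hi`), plus everything [run_comparison()]'s `config` takes.
#' @return Invisibly, the output directory; the comparison result is
#'   attached as attribute `"comparison"`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(
    list(seed = 1L, out_dir = tempfile("uavlai_run_"), input_csv = NULL,
         n_plots = 44L, trim = list(k_lo = 3L, k_hi = 96L)),
    config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  logline("uavlai ", as.character(utils::packageVersion("uavlai")),
          " | R ", R.version.string, " | seed ", cfg$seed)
  write_config(cfg[!vapply(cfg, is.null, logical(1))],
               file.path(cfg$out_dir, "config.json"))

  if (!is.null(cfg$input_csv)) {
    logline("loading spectra from ", cfg$input_csv)
    spectra <- read_spectra_csv(cfg$input_csv)
  } else {
    logline("simulating campaign: ", cfg$n_plots, " plots")
    sim <- simulate_dataset(n_plots = cfg$n_plots, seed = cfg$seed)
    spectra <- sim$spectra
    write_spectra_csv(spectra, file.path(cfg$out_dir, "spectra.csv"))
  }
  trimmed <- trim_reliable(spectra, cfg$trim$k_lo, cfg$trim$k_hi)
  logline("trimmed to ", trimmed$grid$n_bands, " bands (",
          trimmed$grid$start_nm, "-",
          band_wavelength(trimmed$grid, trimmed$grid$n_bands), " nm)")

  cmp_cfg <- cfg[setdiff(names(cfg),
                         c("out_dir", "input_csv", "n_plots", "trim"))]
  cmp <- run_comparison(trimmed, config = cmp_cfg)
  ok <- cmp$table$status == "ok"
  logline(sum(ok), "/", nrow(cmp$table), " comparison rows completed")
  if (!any(ok)) stop("pipeline failed: no comparison row completed", call. = FALSE)

  write_comparison_csv(cmp, file.path(cfg$out_dir, "comparison.csv"))
  for (vs in names(cmp$selections)) {
    write_selection_json(cmp$selections[[vs]],
                         file.path(cfg$out_dir, paste0("selection_", vs, ".json")))
  }
  for (key in names(cmp$models)) {
    save_model(cmp$models[[key]],
               file.path(cfg$out_dir, paste0("model_", key, ".json")))
  }
  # scatter data for the best validation row
  done <- cmp$table[ok, ]
  best <- done[which.max(done$val_r2), ]
  key <- paste(best$method, best$variable_set, sep = ".")
  mdl <- cmp$models[[key]]
  idx <- match(mdl$wavelengths, grid_wavelengths(trimmed$grid))
  sp <- cmp$split
  scat <- rbind(
    data.frame(set = "calibration",
               measured = trimmed$lai[sp$calibration],
               predicted = predict(mdl, trimmed$reflectance[sp$calibration, idx, drop = FALSE])),
    data.frame(set = "validation",
               measured = trimmed$lai[sp$validation],
               predicted = predict(mdl, trimmed$reflectance[sp$validation, idx, drop = FALSE])))
  utils::write.csv(scat, file.path(cfg$out_dir, "scatter_best_model.csv"),
                   row.names = FALSE)
  logline("best row: ", key, " (validation R2 ",
          sprintf("%.3f", best$val_r2), ")")
  structure(invisible(cfg$out_dir), comparison = cmp)
}

#' Simulate a small hyperspectral image cube
#'
#' Builds a `rows x cols x n_bands` reflectance array from a known LAI
#' field: every pixel's spectrum is the closed-form canopy model resampled
#' onto `grid`, plus per-pixel noise. Used to demonstrate per-pixel LAI
#' mapping with a known ground truth.
#'
#' @param lai_field Numeric matrix of true LAI per pixel (values > 0).
#' @param n_rate Nitrogen rate for the canopy model (default 225).
#' @param grid Target [band_grid()] (default [uhd_grid()]).
#' @param noise_sd Per-band noise SD (default 0.002).
#' @param seed RNG seed.
#' @return A list: `cube` (3-d array), `grid`, `lai_field`.
#' @export
simulate_cube <- function(lai_field, n_rate = 225, grid = uhd_grid(),
                          noise_sd = 0.002, seed = 1L) {
  lai_field <- as.matrix(lai_field)
  if (any(lai_field <= 0)) stop("`lai_field` must be positive", call. = FALSE)
  nr <- nrow(lai_field); nc <- ncol(lai_field)
  # resampling is linear in reflectance, so resample the closed-form
  # endmembers once and mix per pixel on the band grid
  soil <- resample_to_grid(
    fine_spectrum(400:1000, soil_reflectance(400:1000)), grid)
  canopy <- resample_to_grid(
    fine_spectrum(400:1000,
                  pmin(pmax(canopy_layer_reflectance(400:1000, n_rate), 0), 1)),
    grid)
  frac <- exp(-0.5 * as.vector(lai_field))
  flat <- outer(frac, soil) + outer(1 - frac, canopy)
  if (noise_sd > 0) {
    flat <- with_seed(seed, flat + stats::rnorm(length(flat), 0, noise_sd))
  }
  cube <- array(flat, dim = c(nr, nc, grid$n_bands))
  list(cube = cube, grid = grid, lai_field = lai_field)
}

#' Per-pixel LAI prediction over an image cube
#'
#' Applies a fitted model to every pixel spectrum of a cube, selecting the
#' model's training wavelengths from the cube's bands. Pixels with any band
#' outside \[0, 1\] are masked (returned as NA).
#'
#' @param model A `fitted_model`.
#' @param cube 3-d array `rows x cols x n_bands` (or the list returned by
#'   [simulate_cube()]).
#' @param grid The cube's [band_grid()] (taken from the list if present).
#' @return A numeric matrix of predicted LAI (NA where masked).
#' @export
predict_map <- function(model, cube, grid = NULL) {
  stopifnot(inherits(model, "fitted_model"))
  if (is.list(cube) && !is.null(cube$cube)) {
    grid <- cube$grid
    cube <- cube$cube
  }
  stopifnot(inherits(grid, "band_grid"))
  d <- dim(cube)
  if (length(d) != 3L || d[3] != grid$n_bands) {
    stop(sprintf("cube band count (%s) does not match grid (%d bands)",
                 if (length(d) == 3L) d[3] else "?", grid$n_bands),
         call. = FALSE)
  }
  wl <- grid_wavelengths(grid)
  idx <- match(model$wavelengths, wl)
  if (any(is.na(idx))) {
    stop(sprintf("model wavelengths missing from cube: %s",
                 paste(model$wavelengths[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  flat <- matrix(cube, nrow = d[1] * d[2], ncol = d[3])
  valid <- rowSums(flat < 0 | flat > 1) == 0
  out <- rep(NA_real_, d[1] * d[2])
  if (any(valid)) {
    Xp <- flat[valid, idx, drop = FALSE]
    colnames(Xp) <- paste0("w", model$wavelengths)
    out[valid] <- predict(model, Xp)
  }
  matrix(out, d[1], d[2])
}
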