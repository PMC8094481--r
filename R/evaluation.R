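#' Accuracy metrics: R2, RMSE, RPD
#'
#' `r_squared` is the squared Pearson correlation between measured and
#' predicted values, `[sum((x - xbar)(y - ybar))]^2 /
#' [sum((x - xbar)^2) sum((y - ybar)^2)]`. `rmse` is
#' `sqrt(sum((y - x)^2) / n)`. `rpd` is the sample standard deviation of the
#' measured values (n - 1 denominator) divided by the RMSE.
#'
#' @param x Measured values (LAI).
#' @param y Predicted values.
#' @return A dimensionless scalar (`rmse` is in LAI units).
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' @rdname r_squared
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (!length(x)) stop("empty input", call. = FALSE)
  sqrt(mean((y - x)^2))
}

#' @param rmse_value A positive RMSE in the units of `x`.
#' @param cap Sentinel value reported when `rmse_value` is zero
#'   (default 1e6).
#' @rdname r_squared
#' @export
rpd <- function(x, rmse_value, cap = 1e6) {
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (rmse_value < 0) stop("rmse must be non-negative", call. = FALSE)
  if (rmse_value == 0) {
    warning("zero RMSE: RPD reported as capped sentinel", call. = FALSE)
    return(cap)
  }
  stats::sd(x) / rmse_value
}

#' Qualitative RPD class
#'
#' Bands: (1.0, 1.4) poor; (1.4, 1.8) usable for correlation assessment;
#' (1.8, 2.0) quantitative prediction; (2.0, 2.5) accurate quantitative
#' prediction; above 2.5 better still. Boundary points go to the upper
#' class; values at or below 1.0 are reported as `"below-scale"`.
#'
#' @param rpd_value Positive RPD.
#' @return A character class label.
#' @export
rpd_class <- function(rpd_value) {
  stopifnot_scalar_number(rpd_value, "rpd_value")
  if (rpd_value <= 0) stop("RPD must be positive", call. = FALSE)
  if (rpd_value <= 1.0) return("below-scale")
  if (rpd_value < 1.4) return("poor")
  if (rpd_value < 1.8) return("correlation-assessment")
  if (rpd_value < 2.0) return("quantitative")
  if (rpd_value < 2.5) return("accurate-quantitative")
  "better"
}

#' Area-based calibration/validation split
#'
#' Experimental areas 1 and 3 form the calibration set, area 2 the
#' standalone validation set; samples flagged unusable are excluded first.
#' The split by whole areas (not random rows) tests robustness across field
#' position.
#'
#' @param samples A data.frame with an `area` column in {1, 2, 3} and
#'   optionally a logical `quality_flag`.
#' @return A list with logical index vectors `calibration` and `validation`
#'   relative to the rows of `samples`.
#' @export
split_by_area <- function(samples) {
  if (!"area" %in% names(samples)) stop("samples need an `area` column", call. = FALSE)
  usable <- if ("quality_flag" %in% names(samples)) samples$quality_flag else TRUE
  cal <- usable & samples$area %in% c(1L, 3L)
  val <- usable & samples$area == 2L
  if (!any(val)) stop("split error: validation set (area 2) is empty", call. = FALSE)
  if (!any(cal)) stop("split error: calibration set (areas 1, 3) is empty", call. = FALSE)
  list(calibration = cal, validation = val)
}

#' Evaluate predictions on one set
#'
#' @param x Measured LAI.
#' @param y Predicted LAI.
#' @return A one-row data.frame: `n`, `r2`, `rmse`, `rpd`, `rpd_class`.
#' @export
evaluation_report <- function(x, y) {
  rm_ <- rmse(x, y)
  rp <- rpd(x, rm_)
  data.frame(n = length(x), r2 = r_squared(x, y), rmse = rm_, rpd = rp,
             rpd_class = rpd_class(rp), stringsAsFactors = FALSE)
}

fit_method <- function(method, X, y, ids, wavelengths, cv_folds, seed, grids) {
  spec <- model_spec(method, grid = grids[[method]], cv_folds = cv_folds,
                     seed = seed)
  switch(method,
         PLSR = fit_plsr(X, y, spec, ids = ids, wavelengths = wavelengths),
         SVR = fit_svr(X, y, spec, ids = ids, wavelengths = wavelengths),
         GBT = fit_gbt(X, y, spec, ids = ids, wavelengths = wavelengths))
}

#' Run the full variable-set x method comparison
#'
#' Builds the five variable sets (Full_spectrum, FD, SPA, CARS, CARS_SPA) on
#' the calibration samples only, fits the three regression methods on each,
#' and evaluates calibration and validation accuracy, yielding the 15-row
#' comparison table. A selector or model failure marks its row `failed`
#' without aborting the rest.
#'
#' @param spectra A trimmed [spectra_set()] carrying LAI and metadata with
#'   `area` (and optionally `quality_flag`, `sample_id`).
#' @param lai Optional LAI override (default `spectra$lai`).
#' @param config Optional named list: `methods`, `variable_sets`,
#'   `fd_threshold`, `spa` / `cars` parameter lists, `model_grids`,
#'   `cv_folds`, `seed`.
#' @return A list of class `comparison_table`: `table` (the 15-row
#'   data.frame), `selections` (the `selection_result`s), `models` (the
#'   `fitted_model`s keyed `method.variable_set`), `split`.
#' @export
run_comparison <- function(spectra, lai = NULL, config = list()) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(lai)) lai <- spectra$lai
  if (is.null(lai)) stop("no LAI available", call. = FALSE)
  cfg <- utils::modifyList(
    list(methods = c("PLSR", "SVR", "GBT"),
         variable_sets = c("Full_spectrum", "FD", "SPA", "CARS", "CARS_SPA"),
         fd_threshold = 0.6, spa = list(), cars = list(),
         model_grids = list(PLSR = NULL, SVR = NULL, GBT = NULL),
         cv_folds = 5L, seed = 1L),
    config)
  meta <- spectra$metadata
  sp <- split_by_area(meta)
  ids <- if ("sample_id" %in% names(meta)) meta$sample_id else seq_len(nrow(meta))
  X <- spectra$reflectance
  wl <- grid_wavelengths(spectra$grid)
  Xcal <- X[sp$calibration, , drop = FALSE]
  ycal <- lai[sp$calibration]
  Xval <- X[sp$validation, , drop = FALSE]
  yval <- lai[sp$validation]
  cal_set <- subset_samples(spectra, sp$calibration)
  cal_set$lai <- ycal

  spa_defaults <- utils::modifyList(list(k_min = 5L, k_max = ncol(X),
                                         seed = cfg$seed), cfg$spa)
  cars_defaults <- utils::modifyList(list(seed = cfg$seed), cfg$cars)

  select_bands <- function(vs) {
    switch(vs,
      Full_spectrum = list(idx = seq_len(ncol(X)), sel = NULL),
      FD = {
        fd <- first_derivative(cal_set)
        corr <- correlation_spectrum(fd, ycal)
        picks <- fd_select_bands(corr, cfg$fd_threshold)
        if (!length(picks)) stop("FD selected no bands", call. = FALSE)
        list(idx = match(corr$wavelength[picks], wl), sel = NULL)
      },
      SPA = {
        s <- do.call(spa_select, c(list(X = Xcal, y = ycal, wavelengths = wl),
                                   spa_defaults))
        list(idx = s$selected_indices, sel = s)
      },
      CARS = {
        s <- do.call(cars_select, c(list(X = Xcal, y = ycal, wavelengths = wl),
                                    cars_defaults))
        list(idx = s$selected_indices, sel = s)
      },
      CARS_SPA = {
        s <- cars_spa_select(Xcal, ycal, spa_params = spa_defaults,
                             cars_params = cars_defaults, wavelengths = wl)
        list(idx = s$selected_indices, sel = s)
      })
  }

  rows <- list(); selections <- list(); models <- list()
  band_sets <- list()
  for (vs in cfg$variable_sets) {
    band_sets[[vs]] <- tryCatch(select_bands(vs), error = function(e) e)
    if (!inherits(band_sets[[vs]], "error") && !is.null(band_sets[[vs]]$sel)) {
      selections[[vs]] <- band_sets[[vs]]$sel
    }
  }
  for (m in cfg$methods) {
    for (vs in cfg$variable_sets) {
      bs <- band_sets[[vs]]
      row <- data.frame(method = m, variable_set = vs,
                        n_wavelengths = NA_integer_,
                        cal_r2 = NA_real_, cal_rmse = NA_real_, cal_rpd = NA_real_,
                        val_r2 = NA_real_, val_rmse = NA_real_, val_rpd = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
      res <- tryCatch({
        if (inherits(bs, "error")) stop(conditionMessage(bs))
        idx <- bs$idx
        fitm <- fit_method(m, Xcal[, idx, drop = FALSE], ycal,
                           ids = ids[sp$calibration], wavelengths = wl[idx],
                           cv_folds = cfg$cv_folds, seed = cfg$seed,
                           grids = cfg$model_grids)
        models[[paste(m, vs, sep = ".")]] <- fitm
        pc <- predict(fitm, Xcal[, idx, drop = FALSE])
        pv <- predict(fitm, Xval[, idx, drop = FALSE])
        ec <- evaluation_report(ycal, pc)
        ev <- evaluation_report(yval, pv)
        row$n_wavelengths <- length(idx)
        row$cal_r2 <- ec$r2; row$cal_rmse <- ec$rmse; row$cal_rpd <- ec$rpd
        row$val_r2 <- ev$r2; row$val_rmse <- ev$rmse; row$val_rpd <- ev$rpd
        row
      }, error = function(e) {
        row$status <- paste("failed:", conditionMessage(e))
        row
      })
      rows[[paste(m, vs)]] <- res
    }
  }
  out <- list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              selections = selections, models = models, split = sp)
  class(out) <- "comparison_table"
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  tb <- x$table
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(v) round(v, 3))
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as CSV
#'
#' Column order follows the comparison-report convention: method, variable
#' set, wavelength count, then calibration and validation R2/RMSE/RPD.
#'
#' @param x A `comparison_table` (or its `table` data.frame).
#' @param path Output CSV path.
#' @export
write_comparison_csv <- function(x, path) {
  tb <- if (inherits(x, "comparison_table")) x$table else x
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
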