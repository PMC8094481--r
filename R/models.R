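#' Model specification for the three regression back-ends
#'
#' Bundles a method name, its hyperparameter grid, the CV fold count for the
#' grid search and a seed. Grid search is k-fold CV on the calibration data
#' only; folds are keyed to sample ids so row order never matters.
#'
#' Default grids: PLSR components 1..15; SVR cost {0.1, 1, 10, 100} x
#' gamma {1e-3, 1e-2, 1e-1, 1}; GBT a compact grid over n_estimators
#' {100, 300}, max_depth {2, 3}, min_child_weight {1, 3}, gamma {0},
#' subsample {0.8, 1}, colsample_bytree {1}, learning_rate {0.05, 0.1}
#' (kept small so the full 15-model comparison runs at desk scale; widen it
#' through `grid` when compute allows).
#'
#' @param method One of `"PLSR"`, `"SVR"`, `"GBT"`.
#' @param grid Named list of hyperparameter vectors; `NULL` uses the default
#'   grid for the method. All grid dimensions must be non-empty.
#' @param cv_folds Folds for the grid-search CV (default 5, minimum 2).
#' @param seed Seed for fold assignment and any stochastic fitting.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("PLSR", "SVR", "GBT"), grid = NULL,
                       cv_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  if (cv_folds < 2L) stop("cv_folds must be at least 2", call. = FALSE)
  if (is.null(grid)) {
    grid <- switch(method,
      PLSR = list(ncomp = 1:15),
      SVR = list(cost = c(0.1, 1, 10, 100), gamma = c(1e-3, 1e-2, 1e-1, 1)),
      GBT = list(n_estimators = c(100L, 300L), max_depth = c(2L, 3L),
                 min_child_weight = c(1, 3), gamma = 0,
                 subsample = c(0.8, 1), colsample_bytree = 1,
                 learning_rate = c(0.05, 0.1)))
  }
  if (!length(grid) || any(!lengths(grid))) {
    stop("hyperparameter grid has an empty dimension", call. = FALSE)
  }
  if (method == "SVR" && any(unlist(grid[c("cost", "gamma")]) <= 0)) {
    stop("SVR grid entries must be positive", call. = FALSE)
  }
  structure(list(method = method, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "model_spec")
}

# Canonical row order keyed to sample ids, so fitting is invariant to row
# permutation of (X, y, ids).
canonical_order <- function(ids, n) {
  if (is.null(ids)) return(seq_len(n))
  order(as.character(ids))
}

# Shared grid-search driver. fit1(X, y, params) -> fit; pred1(fit, X) -> num.
grid_search_fit <- function(X, y, spec, ids, fit1, pred1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(ids)) ids <- seq_len(n)
  ord <- canonical_order(ids, n)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; ids <- ids[ord]
  if (stats::var(y) == 0) stop("degenerate target: y is constant", call. = FALSE)
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  fold <- fold_ids(ids, min(spec$cv_folds, n), spec$seed)
  cv_rmse <- rep(NA_real_, nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    params <- as.list(combos[ci, , drop = FALSE])
    sse <- 0; m <- 0; ok <- TRUE
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- tryCatch(fit1(X[tr, , drop = FALSE], y[tr], params),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pr <- pred1(fit, X[!tr, , drop = FALSE])
      sse <- sse + sum((pr - y[!tr])^2); m <- m + sum(!tr)
    }
    if (ok) cv_rmse[ci] <- sqrt(sse / m)
  }
  if (all(is.na(cv_rmse))) stop("grid search failed for every combination", call. = FALSE)
  best <- which.min(cv_rmse)
  params <- as.list(combos[best, , drop = FALSE])
  list(fit = fit1(X, y, params), params = params,
       cv_rmse = cv_rmse[best],
       cv_table = cbind(combos, cv_rmse = cv_rmse))
}

new_fitted_model <- function(spec, gs, wavelengths, extra = list()) {
  structure(c(list(spec = spec, method = spec$method,
                   hyperparameters = gs$params, cv_rmse = gs$cv_rmse,
                   cv_table = gs$cv_table, fit = gs$fit,
                   wavelengths = wavelengths), extra),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("<fitted_model> %s on %d bands | %s | CV RMSE %.4f\n",
              x$method, length(x$wavelengths), hp, x$cv_rmse))
  invisible(x)
}

#' Fit the three LAI regression back-ends
#'
#' All three share the same contract: hyperparameters are grid-searched by
#' k-fold CV on the supplied (calibration) data only, fold assignment is
#' keyed to `ids`, and the fitted model remembers its training band
#' wavelengths so prediction refuses misaligned matrices. `fit_plsr` centres
#' predictors (latent-variable NIPALS regression, component count by minimal
#' CV RMSE); `fit_svr` standardises predictors per band with calibration
#' statistics and fits an RBF epsilon-SVR; `fit_gbt` fits second-order
#' gradient-boosted trees on raw reflectance.
#'
#' @param X Calibration predictor matrix (samples x bands).
#' @param y Calibration LAI vector.
#' @param spec A [model_spec()] of the matching method.
#' @param ids Optional sample ids (default row index) keying CV folds.
#' @param wavelengths Optional band wavelengths (else parsed from column
#'   names).
#' @return A `fitted_model`.
#' @export
fit_plsr <- function(X, y, spec = model_spec("PLSR"), ids = NULL,
                     wavelengths = NULL) {
  stopifnot(spec$method == "PLSR")
  X <- as.matrix(X)
  wl <- resolve_wavelengths(X, wavelengths)
  cap <- min(ncol(X), nrow(X) - 1L)
  spec$grid$ncomp <- spec$grid$ncomp[spec$grid$ncomp <= cap]
  if (!length(spec$grid$ncomp)) spec$grid$ncomp <- cap
  gs <- grid_search_fit(X, y, spec, ids,
    fit1 = function(Xt, yt, p) pls_fit(Xt, yt, p$ncomp),
    pred1 = function(f, Xn) predict(f, Xn))
  new_fitted_model(spec, gs, wl)
}

#' @rdname fit_plsr
#' @export
fit_svr <- function(X, y, spec = model_spec("SVR"), ids = NULL,
                    wavelengths = NULL) {
  stopifnot(spec$method == "SVR")
  X <- as.matrix(X)
  wl <- resolve_wavelengths(X, wavelengths)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  gs <- grid_search_fit(Xs, y, spec, ids,
    fit1 = function(Xt, yt, p) svr_fit(Xt, yt, cost = p$cost, gamma = p$gamma),
    pred1 = function(f, Xn) predict(f, Xn))
  new_fitted_model(spec, gs, wl, extra = list(center = ctr, scale = scl))
}

#' @rdname fit_plsr
#' @export
fit_gbt <- function(X, y, spec = model_spec("GBT"), ids = NULL,
                    wavelengths = NULL) {
  stopifnot(spec$method == "GBT")
  X <- as.matrix(X)
  wl <- resolve_wavelengths(X, wavelengths)
  fit1 <- function(Xt, yt, p) {
    gbt_train_cpp(Xt, yt, as.integer(p$n_estimators), as.integer(p$max_depth),
                  p$min_child_weight, p$gamma, p$subsample,
                  p$colsample_bytree, p$learning_rate, 1.0, spec$seed)
  }
  gs <- grid_search_fit(X, y, spec, ids, fit1,
                        pred1 = function(f, Xn) gbt_predict_cpp(f, Xn))
  new_fitted_model(spec, gs, wl)
}

#' Predict LAI from a fitted model
#'
#' @param object A `fitted_model`.
#' @param newdata Matrix whose columns match the model's training
#'   wavelengths (checked via `"w<nm>"` column names when present, else by
#'   column count).
#' @param ... Unused.
#' @return Numeric vector of predicted LAI, one per row.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cn <- colnames(newdata)
  if (!is.null(cn) && all(grepl("^w[0-9.]+$", cn))) {
    got <- as.numeric(sub("^w", "", cn))
    if (!isTRUE(all.equal(got, object$wavelengths))) {
      off <- union(setdiff(got, object$wavelengths),
                   setdiff(object$wavelengths, got))
      stop(sprintf("wavelength mismatch: offending bands %s",
                   paste(off, collapse = ", ")), call. = FALSE)
    }
  } else if (ncol(newdata) != length(object$wavelengths)) {
    stop(sprintf("wavelength mismatch: model expects %d bands, got %d",
                 length(object$wavelengths), ncol(newdata)), call. = FALSE)
  }
  out <- switch(object$method,
    PLSR = predict(object$fit, newdata),
    SVR = {
      Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
      predict(object$fit, Xs)
    },
    GBT = as.vector(gbt_predict_cpp(object$fit, newdata)))
  if (any(!is.finite(out))) stop("non-finite prediction produced", call. = FALSE)
  out
}

#' Save / load a fitted model
#'
#' Metadata (method, resolved hyperparameters, wavelengths) is stored as
#' readable JSON; the fitted parameters travel as an opaque base64 blob in
#' the same file.
#'
#' @param model A `fitted_model`.
#' @param path File path.
#' @return `load_model` returns the restored `fitted_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  blob <- jsonlite::base64_enc(serialize(
    model[c("fit", "center", "scale")], NULL))
  obj <- list(method = model$method,
              hyperparameters = model$hyperparameters,
              cv_rmse = model$cv_rmse,
              wavelengths = model$wavelengths,
              spec = list(grid = model$spec$grid,
                          cv_folds = model$spec$cv_folds,
                          seed = model$spec$seed),
              blob = blob)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parts <- unserialize(jsonlite::base64_dec(obj$blob))
  spec <- model_spec(obj$method, grid = as.list(obj$spec$grid),
                     cv_folds = obj$spec$cv_folds, seed = obj$spec$seed)
  structure(list(spec = spec, method = obj$method,
                 hyperparameters = as.list(obj$hyperparameters),
                 cv_rmse = obj$cv_rmse, cv_table = NULL,
                 fit = parts$fit, wavelengths = obj$wavelengths,
                 center = parts$center, scale = parts$scale),
            class = "fitted_model")
}
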