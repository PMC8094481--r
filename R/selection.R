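#' Characteristic-band selectors: SPA, CARS and their chain
#'
#' All selectors return a `selection_result`: the chosen band indices
#' (1-based on the input matrix), the matching wavelengths, the minimised
#' score (validation RMSE for SPA, k-fold RMSECV for CARS) and a per-candidate
#' or per-iteration diagnostic trace. All are deterministic given
#' `(inputs, seed)`; ties break toward the lower band index.
#'
#' @name selectors
NULL

selection_result <- function(method, indices, wavelengths, score, trace) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(method = method, selected_indices = indices,
                 selected_wavelengths = wavelengths[indices],
                 score = score, trace = trace),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d bands, score %.4f\n  %s\n",
              x$method, length(x$selected_indices), x$score,
              paste(x$selected_wavelengths, collapse = " ")))
  invisible(x)
}

resolve_wavelengths <- function(X, wavelengths) {
  if (!is.null(wavelengths)) return(as.numeric(wavelengths))
  cn <- colnames(X)
  if (!is.null(cn) && all(grepl("^[wd][0-9.]+$", cn))) {
    return(as.numeric(sub("^[wd]", "", cn)))
  }
  seq_len(ncol(X))
}

# One SPA chain from a starting column: successively add the column with the
# largest projection onto the orthogonal complement of the current span.
spa_chain <- function(X, start, k_max) {
  p <- ncol(X)
  Xp <- X
  chain <- integer(k_max)
  chain[1L] <- start
  for (step in seq_len(k_max)) {
    s <- chain[step]
    v <- Xp[, s]
    vv <- sum(v^2)
    if (vv < 1e-12) { chain <- chain[seq_len(step - 1L)]; break }
    Xp <- Xp - v %*% (crossprod(v, Xp) / vv)     # deflate all columns
    if (step == k_max) break
    norms <- colSums(Xp^2)
    norms[chain[seq_len(step)]] <- -Inf
    nxt <- which.max(norms)                      # first max: lowest index wins
    if (norms[nxt] < 1e-12) { chain <- chain[seq_len(step)]; break }
    chain[step + 1L] <- nxt
  }
  chain[chain != 0L]
}

#' Successive projections algorithm
#'
#' Classic SPA: for every starting column and every chain length
#' `k_min..k_max`, grow a chain of minimally collinear columns by maximising
#' the norm of each candidate's projection onto the orthogonal complement of
#' the chain's span. Every candidate subset is scored by the RMSE of an
#' ordinary multiple linear regression fitted on a seeded calibration split
#' and evaluated on the held-out fraction; the subset with minimal validation
#' RMSE wins. Candidates too large for the calibration split (or rank
#' deficient) are skipped with a warning.
#'
#' @param X Predictor matrix (n x p); columns are spectral bands.
#' @param y Response (LAI), length n.
#' @param k_min,k_max Smallest/largest subset size considered (defaults 5 and
#'   p, the full-spectrum settings).
#' @param val_fraction Held-out fraction for the internal MLR validation
#'   split (default 0.3).
#' @param seed Seed fixing the split.
#' @param wavelengths Optional wavelengths for the columns (else parsed from
#'   column names).
#' @return A `selection_result` with method `"SPA"`; `trace` has one row per
#'   scored candidate (`start`, `k`, `rmse`).
#' @export
spa_select <- function(X, y, k_min = 5L, k_max = ncol(X),
                       val_fraction = 0.3, seed = 1L, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  k_min <- as.integer(k_min); k_max <- as.integer(min(k_max, p))
  if (k_min > k_max) stop("k_min must not exceed k_max", call. = FALSE)
  if (p < k_min) stop("fewer columns than k_min", call. = FALSE)
  wl <- resolve_wavelengths(X, wavelengths)
  n_val <- max(1L, round(val_fraction * n))
  val <- with_seed(seed, sort(sample.int(n, n_val)))
  cal <- setdiff(seq_len(n), val)
  Xc <- X[cal, , drop = FALSE]
  n_cal <- length(cal)
  # centre columns for the projection geometry; MLR uses raw values
  Xg <- sweep(Xc, 2, colMeans(Xc))

  best <- list(rmse = Inf, subset = NULL)
  trace <- vector("list", p)
  skipped <- 0L
  for (start in seq_len(p)) {
    chain <- spa_chain(Xg, start, k_max)
    ks <- seq.int(k_min, min(k_max, length(chain)))
    if (!length(ks) || ks[1L] > length(chain)) next
    rmses <- rep(NA_real_, length(ks))
    for (j in seq_along(ks)) {
      k <- ks[j]
      sub <- chain[seq_len(k)]
      if (k + 1L >= n_cal) { skipped <- skipped + 1L; next }
      A <- cbind(1, Xc[, sub, drop = FALSE])
      fit <- stats::.lm.fit(A, y[cal])
      if (any(is.na(fit$coefficients)) || fit$rank < ncol(A)) {
        skipped <- skipped + 1L
        next
      }
      pred <- cbind(1, X[val, sub, drop = FALSE]) %*% fit$coefficients
      rmses[j] <- sqrt(mean((pred - y[val])^2))
      if (rmses[j] < best$rmse - 1e-15) {
        best <- list(rmse = rmses[j], subset = sub)
      }
    }
    trace[[start]] <- data.frame(start = start, k = ks, rmse = rmses)
  }
  if (skipped > 0L) {
    warning(sprintf("%d SPA candidate(s) skipped (rank deficient or larger than the calibration split)",
                    skipped), call. = FALSE)
  }
  if (is.null(best$subset)) stop("SPA found no scoreable candidate subset", call. = FALSE)
  selection_result("SPA", best$subset, wl, best$rmse, do.call(rbind, trace))
}

# EDF retention schedule: r_i = a * exp(-k i) with a = (p/2)^(1/(N-1)) and
# k = ln(p/2)/(N-1), so r_1 = 1 and r_N = 2/p. Evaluated in log space so the
# endpoint identities hold to machine precision.
cars_edf_ratios <- function(p, n_runs) {
  exp(log(p / 2) * (1 - seq_len(n_runs)) / (n_runs - 1))
}

# ceiling with an absolute fuzz so r_i * p lands on its mathematical integer
ceil_edf <- function(x) ceiling(x - 1e-9)

#' Competitive adaptive reweighted sampling
#'
#' Monte Carlo "survival of the fittest" over wavelength variables. Each run
#' draws a calibration subsample, fits a PLS model on the surviving
#' variables, weights each variable by its absolute PLS coefficient
#' (normalised to sum 1), enforces removal through the exponentially
#' decreasing function (EDF) retention schedule, then applies adaptive
#' reweighted sampling (ARS): weighted draws with replacement among the
#' EDF-retained variables, the distinct drawn ones surviving. The k-fold
#' RMSECV of a PLS model on each run's survivors is recorded and the
#' survivors of the minimum-RMSECV run are returned.
#'
#' @param X Predictor matrix (n x p), p >= 3.
#' @param y Response, length n.
#' @param n_runs Number of EDF iterations (default 50).
#' @param mc_fraction Monte Carlo calibration fraction per run (default 0.8).
#' @param n_folds Folds for RMSECV (default 10).
#' @param max_pls_components Cap on PLS components
#'   (default `min(10, p - 1, n - 1)`).
#' @param seed RNG seed.
#' @param wavelengths Optional column wavelengths.
#' @return A `selection_result` with method `"CARS"`; `trace` has one row per
#'   iteration (`iteration`, `ratio`, `retained_edf`, `n_survivors`,
#'   `rmsecv`) plus an attribute `coefficients` (list of named PLS
#'   coefficient vectors per iteration).
#' @export
cars_select <- function(X, y, n_runs = 50L, mc_fraction = 0.8, n_folds = 10L,
                        max_pls_components = NULL, seed = 1L,
                        wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop("CARS needs at least 3 columns", call. = FALSE)
  if (n_runs < 2L) stop("n_runs must be at least 2", call. = FALSE)
  wl <- resolve_wavelengths(X, wavelengths)
  if (is.null(max_pls_components)) max_pls_components <- min(10L, p - 1L, n - 1L)
  ratios <- cars_edf_ratios(p, n_runs)

  current <- seq_len(p)
  trace <- data.frame(iteration = seq_len(n_runs), ratio = ratios,
                      retained_edf = NA_integer_, n_survivors = NA_integer_,
                      rmsecv = NA_real_)
  coef_log <- vector("list", n_runs)
  survivors_log <- vector("list", n_runs)

  with_seed(seed, {
    for (i in seq_len(n_runs)) {
      n_mc <- ceiling(mc_fraction * n)
      rows <- sample.int(n, n_mc)
      A <- min(max_pls_components, length(current), n_mc - 1L)
      fit <- pls_fit(X[rows, current, drop = FALSE], y[rows], A)
      b <- abs(fit$coef[, fit$ncomp])
      w <- b / sum(b)
      names(w) <- as.character(current)
      coef_log[[i]] <- w
      n_keep <- min(ceil_edf(ratios[i] * p), length(current))
      trace$retained_edf[i] <- n_keep
      keep <- current[order(w, decreasing = TRUE)[seq_len(n_keep)]]
      keep <- sort(keep)
      # ARS: weighted draws with replacement among EDF-retained variables
      wk <- w[as.character(keep)]
      draws <- keep[sample.int(length(keep), ceil_edf(ratios[i] * p),
                               replace = TRUE, prob = wk)]
      surv <- sort(unique(draws))
      survivors_log[[i]] <- surv
      trace$n_survivors[i] <- length(surv)
      if (length(surv) >= 2L) {
        cv <- pls_rmsecv(X[, surv, drop = FALSE], y,
                         min(max_pls_components, length(surv)),
                         n_folds = n_folds, seed = seed + i)
        trace$rmsecv[i] <- suppressWarnings(min(cv, na.rm = TRUE))
      }
      current <- surv
      if (length(current) < 2L) break
    }
  })
  if (all(is.na(trace$rmsecv))) stop("CARS selection failed: no valid run", call. = FALSE)
  best_i <- which.min(trace$rmsecv)
  attr(trace, "coefficients") <- coef_log
  selection_result("CARS", survivors_log[[best_i]], wl,
                   trace$rmsecv[best_i], trace)
}

#' SPA-then-CARS chained selection
#'
#' Runs [spa_select()] on the full (trimmed) matrix, then [cars_select()]
#' restricted to the SPA-selected columns, returning the CARS survivors in
#' the original column indexing. The chain removes SPA's residual noisy
#' picks while keeping its low-collinearity structure.
#'
#' @param X,y As in the component selectors.
#' @param spa_params,cars_params Named lists of arguments forwarded to
#'   [spa_select()] / [cars_select()].
#' @param wavelengths Optional column wavelengths.
#' @return A `selection_result` with method `"CARS_SPA"`; `trace` is a list
#'   with both stages' traces and the SPA-stage indices.
#' @export
cars_spa_select <- function(X, y, spa_params = list(), cars_params = list(),
                            wavelengths = NULL) {
  X <- as.matrix(X)
  wl <- resolve_wavelengths(X, wavelengths)
  spa <- do.call(spa_select, c(list(X = X, y = y, wavelengths = wl), spa_params))
  if (length(spa$selected_indices) < 3L) {
    stop("chaining error: SPA returned fewer than 3 bands", call. = FALSE)
  }
  idx <- spa$selected_indices
  cars <- do.call(cars_select,
                  c(list(X = X[, idx, drop = FALSE], y = y,
                         wavelengths = wl[idx]), cars_params))
  selection_result("CARS_SPA", idx[cars$selected_indices], wl, cars$score,
                   list(spa = spa$trace, spa_indices = idx, cars = cars$trace))
}
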