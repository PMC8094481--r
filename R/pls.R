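#' Partial least squares regression (NIPALS, single response)
#'
#' Fits PLS1 by the NIPALS algorithm and returns regression coefficients for
#' every component count 1..`ncomp` at once, which makes cross-validated
#' component selection cheap. Predictors are centred (optionally unit-scaled)
#' and the response centred using training statistics.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response vector, length n.
#' @param ncomp Maximum number of latent components; capped at
#'   `min(p, n - 1)`.
#' @param scale Scale predictor columns to unit SD (default FALSE).
#' @return An object of class `pls_fit`: `coef` (p x ncomp matrix of
#'   coefficients on the original predictor scale), `intercept` (length
#'   ncomp), `ncomp`, centring/scaling vectors.
#' @export
pls_fit <- function(X, y, ncomp, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y are not aligned", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate target: y is constant", call. = FALSE)
  ncomp <- min(as.integer(ncomp), p, n - 1L)
  if (ncomp < 1L) stop("ncomp must be at least 1", call. = FALSE)
  x_mean <- colMeans(X)
  x_sd <- if (scale) pmax(apply(X, 2, stats::sd), .Machine$double.eps) else rep(1, p)
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  yc <- y - y_mean

  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Xr <- Xc; yr <- yc
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                      # residual orthogonal to X
    w <- w / nw
    t_ <- Xr %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(Xr, t_) / tt
    q[a] <- sum(yr * t_) / tt
    Xr <- Xr - t_ %*% t(p_)
    yr <- yr - q[a] * t_
    W[, a] <- w; P[, a] <- p_
    a_used <- a
  }
  if (a_used == 0L) stop("PLS failed: predictors carry no signal", call. = FALSE)
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # coefficients for each component count, on the original X scale
  R <- W %*% pinv_small(crossprod(P, W))
  B <- apply(R * rep(q, each = p), 1, cumsum)  # a x p
  B <- if (a_used == 1L) matrix(B, nrow = 1L) else B
  coef <- t(B) / x_sd
  intercept <- y_mean - as.vector(x_mean %*% coef)
  structure(list(coef = coef, intercept = intercept, ncomp = a_used,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean),
            class = "pls_fit")
}

# P'W is unit upper triangular in exact arithmetic; use a pseudo-inverse as a
# guard against numerical singularity in deflated late components.
pinv_small <- function(M) {
  s <- svd(M)
  d <- ifelse(s$d > max(s$d) * 1e-10, 1 / s$d, 0)
  s$v %*% (t(s$u) * d)
}

#' @param object A `pls_fit`.
#' @param newdata Matrix with the same columns as the training predictors.
#' @param ncomp Component count to predict with (default: all fitted).
#' @param ... Unused.
#' @rdname pls_fit
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  as.vector(as.matrix(newdata) %*% object$coef[, ncomp] +
              object$intercept[ncomp])
}

#' Cross-validated RMSE of PLS per component count
#'
#' @param X,y Training data.
#' @param ncomp_max Largest component count to evaluate.
#' @param n_folds Number of CV folds.
#' @param ids Sample ids keying the fold assignment (default row index).
#' @param seed Seed for the fold assignment.
#' @return Numeric vector: RMSECV for 1..ncomp_max components (NA where a
#'   component count was unreachable in some fold).
#' @export
pls_rmsecv <- function(X, y, ncomp_max, n_folds = 10L, ids = NULL, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  if (is.null(ids)) ids <- seq_len(n)
  n_folds <- min(n_folds, n)
  fold <- fold_ids(ids, n_folds, seed)
  ncomp_max <- min(ncomp_max, ncol(X), n - max(table(fold)) - 1L)
  if (ncomp_max < 1L) return(NA_real_)
  press <- matrix(0, n_folds, ncomp_max)
  counted <- matrix(FALSE, n_folds, ncomp_max)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp_max)
    for (a in seq_len(min(ncomp_max, fit$ncomp))) {
      pr <- predict(fit, X[!tr, , drop = FALSE], ncomp = a)
      press[f, a] <- sum((pr - y[!tr])^2)
      counted[f, a] <- TRUE
    }
  }
  out <- rep(NA_real_, ncomp_max)
  for (a in seq_len(ncomp_max)) {
    if (all(counted[, a])) out[a] <- sqrt(sum(press[, a]) / n)
  }
  out
}
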