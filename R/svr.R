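#' Epsilon-insensitive support vector regression with an RBF kernel
#'
#' Solves the epsilon-SVR dual by coordinate descent on the box-constrained
#' difference variables `beta_i = alpha_i - alpha_i*` in `[-C, C]`:
#' `min 0.5 b'Kb - y'b + eps * sum|b_i|`. The free offset is absorbed by
#' centring the response (no equality constraint), the standard
#' simplification for kernelised dual coordinate descent. Predictors should
#' be standardised before calling (the [fit_svr()] wrapper does this).
#'
#' @param X Training matrix (n x p).
#' @param y Response, length n.
#' @param cost Box constraint C > 0.
#' @param gamma RBF kernel width, `K(u,v) = exp(-gamma * ||u - v||^2)`.
#' @param epsilon Insensitivity tube half-width (default 0.1).
#' @param tol Convergence tolerance on the largest coordinate move.
#' @param max_passes Maximum full passes over the coordinates.
#' @return An object of class `svr_fit` with the dual coefficients, support
#'   vectors and kernel parameters.
#' @export
svr_fit <- function(X, y, cost = 1, gamma = 0.1, epsilon = 0.1,
                    tol = 1e-5, max_passes = 500L) {
  if (cost <= 0 || gamma <= 0) stop("`cost` and `gamma` must be positive", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  K <- rbf_kernel(X, X, gamma)
  beta <- numeric(n)
  Kbeta <- numeric(n)
  for (pass in seq_len(max_passes)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      q <- Kbeta[i] - K[i, i] * beta[i]
      target <- yc[i] - q
      b_new <- sign(target) * max(abs(target) - epsilon, 0) / K[i, i]
      b_new <- min(max(b_new, -cost), cost)
      d <- b_new - beta[i]
      if (d != 0) {
        Kbeta <- Kbeta + K[, i] * d
        beta[i] <- b_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  sv <- which(beta != 0)
  structure(list(beta = beta[sv], sv = X[sv, , drop = FALSE],
                 y_mean = y_mean, cost = cost, gamma = gamma,
                 epsilon = epsilon, n_sv = length(sv)),
            class = "svr_fit")
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' @param object An `svr_fit`.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @rdname svr_fit
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$n_sv == 0L) return(rep(object$y_mean, nrow(newdata)))
  as.vector(rbf_kernel(newdata, object$sv, object$gamma) %*% object$beta) +
    object$y_mean
}
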