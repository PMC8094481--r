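# Shared fixtures, all generated in code.

# A tiny spectra set on an arbitrary uniform grid.
toy_spectra <- function(n = 6, grid = band_grid(500, 10, 8, 20), seed = 1) {
  refl <- uavlai:::with_seed(seed,
    matrix(runif(n * grid$n_bands, 0.1, 0.6), n, grid$n_bands))
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     area = rep_len(c(1L, 2L, 3L), n))
  spectra_set(refl, grid, metadata = meta,
              lai = uavlai:::with_seed(seed + 1, runif(n, 2, 8)))
}

# Planted-band recovery world: 9 informative independent-information columns
# over a smooth collinear 3-factor background, as real characteristic bands
# carry non-redundant signal while their neighbours are mutually redundant.
planted_bands <- function(seed, n = 124, p = 94,
                          idx = c(3, 7, 18, 26, 39, 51, 64, 78, 90)) {
  uavlai:::with_seed(3000 + seed, {
    L <- matrix(rnorm(n * 3), n, 3)
    load <- sapply(1:3, function(k) sin(seq_len(p) / p * pi * k + k))
    X <- L %*% t(load) * 0.4 + matrix(rnorm(n * p, 0, 0.05), n, p)
    X[, idx] <- matrix(rnorm(n * length(idx)), n)
    beta <- rep_len(c(3, -2.5, 2, 3.5, -3, 2.5, -2, 3, -3.5), length(idx))
    y <- as.vector(X[, idx] %*% beta + rnorm(n, 0, 0.3))
    list(X = X, y = y, idx = idx)
  })
}

# Orthogonal norm-separated design where the SPA chain provably reaches the
# best 2-subset, for exhaustive-oracle equivalence.
ortho_instance <- function(seed, n = 30, p = 8) {
  uavlai:::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
    X <- Q %*% diag(c(4, 3, seq(1, 0.5, length.out = p - 2)))
    y <- 2 * X[, 1] + 1.5 * X[, 2] + rnorm(n, 0, 0.05)
    list(X = X, y = y)
  })
}

# Exhaustive best-subset-by-validation-RMSE oracle sharing spa_select's split.
exhaustive_best_subset <- function(X, y, sizes, seed, val_fraction = 0.3) {
  n <- nrow(X)
  n_val <- max(1L, round(val_fraction * n))
  val <- uavlai:::with_seed(seed, sort(sample.int(n, n_val)))
  cal <- setdiff(seq_len(n), val)
  best <- NULL; best_r <- Inf
  for (k in sizes) {
    for (cmb in utils::combn(ncol(X), k, simplify = FALSE)) {
      fit <- stats::lm.fit(cbind(1, X[cal, cmb, drop = FALSE]), y[cal])
      if (any(is.na(fit$coefficients))) next
      pred <- cbind(1, X[val, cmb, drop = FALSE]) %*% fit$coefficients
      r <- sqrt(mean((pred - y[val])^2))
      if (r < best_r - 1e-15) { best_r <- r; best <- cmb }
    }
  }
  list(subset = best, rmse = best_r)
}
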