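# SPA, CARS and the SPA-then-CARS chain.

test_that("SPA equals exhaustive best-subset search on small instances", {
  for (s in c(1, 4, 10, 15)) {
    inst <- ortho_instance(s)
    spa <- suppressWarnings(
      spa_select(inst$X, inst$y, k_min = 2, k_max = 2, seed = s))
    orc <- exhaustive_best_subset(inst$X, inst$y, sizes = 2, seed = s)
    expect_equal(sort(spa$selected_indices), sort(orc$subset))
    expect_equal(spa$score, orc$rmse, tolerance = 1e-10)
  }
})

test_that("SPA at k_min = k_max = 1 is the exhaustive single best column", {
  inst <- uavlai:::with_seed(5, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    list(X = X, y = X[, 4] * 2 + rnorm(40, 0, 0.2))
  })
  spa <- spa_select(inst$X, inst$y, k_min = 1, k_max = 1, seed = 2)
  orc <- exhaustive_best_subset(inst$X, inst$y, sizes = 1, seed = 2)
  expect_equal(spa$selected_indices, orc$subset)
  expect_equal(spa$score, orc$rmse, tolerance = 1e-10)
})

test_that("a duplicated column never joins a chain with its twin", {
  inst <- ortho_instance(3)
  Xd <- cbind(inst$X, inst$X[, 1])       # column 9 duplicates column 1
  chains <- lapply(seq_len(9), function(s)
    uavlai:::spa_chain(sweep(Xd, 2, colMeans(Xd)), s, 9))
  for (ch in chains) {
    expect_false(all(c(1L, 9L) %in% ch))
  }
})

test_that("SPA validates parameters and is deterministic", {
  inst <- ortho_instance(2)
  expect_error(spa_select(inst$X, inst$y, k_min = 5, k_max = 3), "k_min")
  a <- suppressWarnings(spa_select(inst$X, inst$y, k_min = 2, k_max = 4, seed = 7))
  b <- suppressWarnings(spa_select(inst$X, inst$y, k_min = 2, k_max = 4, seed = 7))
  expect_identical(a$selected_indices, b$selected_indices)
  expect_identical(a$score, b$score)
})

test_that("CARS EDF endpoints are exact for any (p, n_runs)", {
  for (p in c(10, 94, 211)) {
    for (n_runs in c(10, 50, 73)) {
      r <- uavlai:::cars_edf_ratios(p, n_runs)
      expect_equal(r[1] * p, p, tolerance = 1e-9)
      expect_equal(uavlai:::ceil_edf(r[n_runs] * p), 2)
      expect_true(all(diff(uavlai:::ceil_edf(r * p)) <= 0))  # retained count monotone
    }
  }
})

test_that("CARS recovers 5 planted columns of 60 in >= 18/20 seeded runs", {
  hits <- vapply(1:20, function(s) {
    d <- uavlai:::with_seed(1000 + s, {
      X <- matrix(rnorm(100 * 60), 100, 60)
      idx <- c(5, 17, 28, 41, 55)
      y <- as.vector(X[, idx] %*% c(3, -2.5, 2, 3.5, -3) + rnorm(100, 0, 0.3))
      list(X = X, y = y, idx = idx)
    })
    sel <- cars_select(d$X, d$y, seed = s)
    all(d$idx %in% sel$selected_indices)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("CARS trace is well-formed and the selection deterministic", {
  d <- planted_bands(1, n = 60, p = 30, idx = c(4, 11, 19, 23, 28))
  sel <- cars_select(d$X, d$y, n_runs = 30, seed = 5)
  tr <- sel$trace
  expect_true(all(diff(tr$retained_edf[!is.na(tr$retained_edf)]) <= 0))
  expect_equal(tr$retained_edf[1], 30)      # r_1 keeps all variables
  expect_equal(sel$score, min(tr$rmsecv, na.rm = TRUE))
  sel2 <- cars_select(d$X, d$y, n_runs = 30, seed = 5)
  expect_identical(sel$selected_indices, sel2$selected_indices)
  expect_error(cars_select(d$X[, 1:2], d$y), "at least 3")
})

test_that("the chain equals CARS applied to the SPA subset and stays inside it", {
  d <- planted_bands(2, n = 80, p = 40, idx = c(4, 12, 21, 30, 38))
  chained <- suppressWarnings(cars_spa_select(
    d$X, d$y, spa_params = list(k_min = 5, k_max = 15, seed = 3),
    cars_params = list(n_runs = 30, seed = 3)))
  spa <- suppressWarnings(
    spa_select(d$X, d$y, k_min = 5, k_max = 15, seed = 3))
  expect_true(all(chained$selected_indices %in% spa$selected_indices))
  direct <- cars_select(d$X[, spa$selected_indices, drop = FALSE], d$y,
                        n_runs = 30, seed = 3)
  expect_identical(chained$selected_indices,
                   spa$selected_indices[direct$selected_indices])
  expect_equal(chained$score, direct$score)
})

test_that("selected subsets never degrade calibration RMSE versus the intercept", {
  sim <- simulate_dataset(n_plots = 16, seed = 21)
  tr <- trim_reliable(sim$spectra)
  X <- tr$reflectance; y <- tr$lai
  base_rmse <- sqrt(mean((y - mean(y))^2))
  sel <- suppressWarnings(spa_select(X, y, k_min = 3, k_max = 10, seed = 1))
  fit <- fit_plsr(X[, sel$selected_indices, drop = FALSE], y)
  expect_lte(rmse(y, predict(fit, X[, sel$selected_indices, drop = FALSE])),
             base_rmse)
})

test_that("PLS core: full-component fit equals OLS and 1 column equals the LS line", {
  d <- uavlai:::with_seed(8, {
    X <- matrix(rnorm(40 * 5), 40, 5)
    list(X = X, y = as.vector(X %*% c(1, -2, 0.5, 0, 3) + rnorm(40, 0, 0.1)))
  })
  f <- pls_fit(d$X, d$y, 5)
  ols <- stats::lm.fit(cbind(1, d$X), d$y)
  expect_equal(predict(f, d$X), as.vector(cbind(1, d$X) %*% ols$coefficients),
               tolerance = 1e-6)
  x1 <- d$X[, 1, drop = FALSE]
  f1 <- pls_fit(x1, d$y, 1)
  line <- stats::lm.fit(cbind(1, x1), d$y)$coefficients
  expect_equal(unname(f1$coef[, 1]), unname(line[2]), tolerance = 1e-8)
  expect_equal(unname(f1$intercept[1]), unname(line[1]), tolerance = 1e-8)
})
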