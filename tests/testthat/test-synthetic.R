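# The synthetic campaign generator: design, LAI, canopy spectra.

test_that("simulate_design balances combinations and is deterministic", {
  d48 <- simulate_design(48, seed = 1)
  expect_equal(nrow(d48), 48)
  tab <- table(d48$cultivar, d48$n_treatment)
  expect_true(all(tab == 3))                       # each combo 3x
  expect_equal(sort(unique(d48$area)), 1:3)
  per_area <- table(d48$area, paste(d48$cultivar, d48$n_treatment))
  expect_true(all(per_area == 1))                  # full replicate per area

  d44 <- simulate_design(44, seed = 1)
  expect_equal(nrow(d44), 44)
  expect_equal(nrow(unique(d44[, c("cultivar", "n_treatment")])), 16)
  expect_equal(sort(unique(d44$area)), 1:3)

  expect_identical(simulate_design(44, seed = 9), simulate_design(44, seed = 9))
  expect_error(simulate_design(12), "invalid design")
})

test_that("simulate_lai bookkeeping: 132 samples, 8 flagged, 124 usable", {
  d <- simulate_design(44, seed = 1)
  l <- simulate_lai(d, seed = 1)
  expect_equal(nrow(l), 132)
  expect_equal(sum(!l$quality_flag), 8)
  expect_equal(sum(l$quality_flag), 124)
  expect_true(all(l$lai > 0))
  expect_error(simulate_lai(d, sigma = -1), "sigma")
})

test_that("LAI peaks at booting and responds to nitrogen with a high-N plateau", {
  d <- simulate_design(48, seed = 2)
  l <- simulate_lai(d, seed = 2, n_flagged = 0)
  m <- tapply(l$lai, l$stage, mean)
  expect_gt(m[["booting"]], m[["jointing"]])
  expect_gt(m[["booting"]], m[["filling"]])
  g <- tapply(l$lai, l$n_treatment, mean)
  expect_gt(g[["N8"]], g[["N0"]])
  expect_gt(g[["N15"]], g[["N8"]])
  # plateau: N15 and N22 close relative to the N0 -> N15 rise
  expect_lt(abs(g[["N22"]] - g[["N15"]]), 0.3 * (g[["N15"]] - g[["N0"]]))
})

test_that("pooled usable LAI matches the stated moments over 20 seeds", {
  stats_by_seed <- vapply(1:20, function(s) {
    l <- simulate_lai(simulate_design(44, s), seed = s + 100)
    u <- l$lai[l$quality_flag]
    c(mean(u), stats::sd(u), min(u), max(u))
  }, numeric(4))
  expect_gt(mean(stats_by_seed[1, ]), 5.0)
  expect_lt(mean(stats_by_seed[1, ]), 5.9)
  expect_gt(mean(stats_by_seed[2, ]), 1.4)
  expect_lt(mean(stats_by_seed[2, ]), 2.0)
  expect_true(all(stats_by_seed[3, ] >= 1.5))
  expect_true(all(stats_by_seed[4, ] <= 8.8))
})

test_that("canopy spectra have the red valley, stay in [0,1], and converge to the canopy layer", {
  f <- simulate_canopy_spectrum(5, 225, noise_sd = 0)
  wl <- f$wavelengths
  win <- wl >= 650 & wl <= 700
  valley <- wl[win][which.min(f$reflectance[win])]
  expect_gte(valley, 668)
  expect_lte(valley, 680)
  noisy <- simulate_canopy_spectrum(5, 225, seed = 1, noise_sd = 0.05)
  expect_true(all(noisy$reflectance >= 0 & noisy$reflectance <= 1))
  # large-LAI limit: soil term vanishes
  big <- simulate_canopy_spectrum(60, 225, noise_sd = 0)
  canopy <- uavlai:::canopy_layer_reflectance(wl, 225)
  expect_equal(big$reflectance, pmin(pmax(canopy, 0), 1), tolerance = 1e-9)
  expect_error(simulate_canopy_spectrum(-1, 225), "positive")
  expect_error(simulate_canopy_spectrum(5, 100), "n_rate")
})

test_that("nitrogen orderings hold: visible decreasing, NIR increasing", {
  wl <- 400:1000
  vis_means <- nir_means <- numeric(4)
  for (i in seq_along(c(0, 120, 225, 330))) {
    nr <- c(0, 120, 225, 330)[i]
    r <- simulate_canopy_spectrum(5, nr, noise_sd = 0)$reflectance
    vis_means[i] <- mean(r[wl >= 458 & wl <= 730])
    nir_means[i] <- mean(r[wl >= 790 & wl <= 830])
  }
  expect_true(all(diff(vis_means) < 0))   # N0 > N8 > N15 > N22
  expect_true(all(diff(nir_means) > 0))   # N22 > N15 > N8 > N0
})

test_that("noise-free NIR is strictly increasing in LAI at fixed nitrogen", {
  wl <- 400:1000
  nir <- vapply(c(1, 2, 3.5, 5, 6.5, 8), function(L) {
    r <- simulate_canopy_spectrum(L, 120, noise_sd = 0)$reflectance
    mean(r[wl >= 790 & wl <= 830])
  }, numeric(1))
  expect_true(all(diff(nir) > 0))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_dataset(n_plots = 16, seed = 11)
  b <- simulate_dataset(n_plots = 16, seed = 11)
  expect_identical(a$spectra$reflectance, b$spectra$reflectance)
  expect_identical(a$samples, b$samples)
  s1 <- simulate_canopy_spectrum(4.2, 330, seed = 3)
  s2 <- simulate_canopy_spectrum(4.2, 330, seed = 3)
  expect_identical(s1$reflectance, s2$reflectance)
})
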