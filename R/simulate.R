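#' Synthetic field experiment: design, LAI, canopy spectra
#'
#' The generator emulates a winter-wheat nitrogen trial: 4 cultivars x 4
#' nitrogen treatments replicated across 3 experimental areas, sampled at
#' three growth stages (jointing, booting, filling), with canopy reflectance
#' responding to LAI and nitrogen. It exists so the whole band-selection and
#' regression pipeline can be exercised and tested without field data.
#'
#' @name synthetic
NULL

WHEAT_CULTIVARS <- c("AK58", "ZM27", "XN509", "YM49-198")
N_TREATMENTS <- c(N0 = 0, N8 = 120, N15 = 225, N22 = 330)
GROWTH_STAGES <- c("jointing", "booting", "filling")

#' Simulate the experimental design
#'
#' Plots are filled replicate by replicate: each complete block of the 16
#' cultivar x nitrogen combinations is assigned to one area (cycling through
#' areas 1, 2, 3), and any remainder plots draw a seeded subset of
#' combinations into the next area. With `n_plots = 48` every area holds a
#' full replicate; the default 44 covers all 16 combinations across 3 areas.
#'
#' @param n_plots Total number of plots, at least 16 (default 44).
#' @param seed RNG seed; the design is deterministic given `(n_plots, seed)`.
#' @return A data.frame with columns `plot_id`, `cultivar`, `n_treatment`
#'   (factor N0/N8/N15/N22), `n_rate` (kg/ha), `area`.
#' @export
simulate_design <- function(n_plots = 44L, seed = 1L) {
  n_plots <- as.integer(n_plots)
  if (is.na(n_plots) || n_plots < 16L) {
    stop("invalid design: need at least 16 plots to cover all cultivar x nitrogen combinations",
         call. = FALSE)
  }
  combos <- expand.grid(cultivar = WHEAT_CULTIVARS,
                        n_treatment = names(N_TREATMENTS),
                        stringsAsFactors = FALSE)
  # round-robin over combinations and areas: because gcd(3, 16) = 1, a
  # 48-plot design places every combination exactly once in every area, and
  # any n >= 16 covers all 16 combinations across the 3 areas
  i <- seq_len(n_plots)
  des <- combos[(i - 1L) %% 16L + 1L, , drop = FALSE]
  des$area <- (i - 1L) %% 3L + 1L
  # shuffle plot positions within each area, seeded
  des <- with_seed(seed + 1L, {
    ord <- order(des$area, stats::runif(nrow(des)))
    des[ord, , drop = FALSE]
  })
  des$plot_id <- sprintf("P%02d", seq_len(nrow(des)))
  des$n_rate <- unname(N_TREATMENTS[des$n_treatment])
  rownames(des) <- NULL
  des[, c("plot_id", "cultivar", "n_treatment", "n_rate", "area")]
}

# LAI generator defaults: multiplicative stage x nitrogen x cultivar effects
# with lognormal plot noise, tuned once so the pooled usable sample has
# mean ~5.4 and SD ~1.7 within [1.5, 8.8].
LAI_STAGE_BASE <- c(jointing = 4.30, booting = 7.00, filling = 4.90)
LAI_N_EFFECT <- c(N0 = 0.68, N8 = 0.94, N15 = 1.15, N22 = 1.17)
LAI_CULTIVAR_EFFECT <- c("AK58" = 0.96, "ZM27" = 0.99,
                         "XN509" = 1.02, "YM49-198" = 1.04)

#' Simulate LAI for every plot x stage sample
#'
#' LAI follows `base(stage) * g(N) * cultivar_factor * exp(eps)` with
#' `eps ~ N(0, sigma^2)`: it peaks at booting, increases with nitrogen with a
#' plateau between the two highest rates, and is clamped to \[1.6, 8.7\] so
#' the pooled sample stays inside the field-realistic range. A seeded random
#' subset of samples (default 8) is flagged unusable, mimicking measurement
#' failures.
#'
#' @param design Output of [simulate_design()].
#' @param seed RNG seed.
#' @param sigma Lognormal noise SD (default 0.12); must be non-negative.
#' @param n_flagged Number of samples to flag `quality_flag = FALSE`
#'   (default 8).
#' @return A data.frame with one row per plot x stage: `sample_id`,
#'   `plot_id`, `stage`, `cultivar`, `n_treatment`, `n_rate`, `area`, `lai`,
#'   `quality_flag`.
#' @export
simulate_lai <- function(design, seed = 1L, sigma = 0.12, n_flagged = 8L) {
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  samp <- merge(design,
                data.frame(stage = GROWTH_STAGES, stringsAsFactors = FALSE))
  samp <- samp[order(match(samp$stage, GROWTH_STAGES), samp$plot_id), ]
  n <- nrow(samp)
  mu <- LAI_STAGE_BASE[samp$stage] * LAI_N_EFFECT[samp$n_treatment] *
    LAI_CULTIVAR_EFFECT[samp$cultivar]
  eps <- with_seed(seed, stats::rnorm(n, 0, sigma))
  samp$lai <- pmin(pmax(unname(mu) * exp(eps), 1.6), 8.7)
  samp$quality_flag <- TRUE
  n_flagged <- min(as.integer(n_flagged), n)
  if (n_flagged > 0L) {
    bad <- with_seed(seed + 1L, sample.int(n, n_flagged))
    samp$quality_flag[bad] <- FALSE
  }
  samp$sample_id <- sprintf("%s_%s", samp$plot_id, samp$stage)
  rownames(samp) <- NULL
  samp[, c("sample_id", "plot_id", "stage", "cultivar", "n_treatment",
           "n_rate", "area", "lai", "quality_flag")]
}

# Noise-free canopy-layer reflectance (before soil mixing) on `wl` nm.
canopy_layer_reflectance <- function(wl, n_rate) {
  c_n <- n_rate / 330                       # nitrogen level scaled to [0, 1]
  vis_base <- 0.120 - 0.030 * c_n           # visible albedo, decreasing in N
  green <- 0.060 * exp(-((wl - 550)^2) / (2 * 20^2))
  blue_well <- -(0.030 + 0.020 * c_n) * exp(-((wl - 470)^2) / (2 * 25^2))
  red_well <- -(0.050 + 0.025 * c_n) * exp(-((wl - 674)^2) / (2 * 18^2))
  vis <- vis_base + green + blue_well + red_well
  nir <- 0.42 + 0.10 * c_n                  # NIR plateau, increasing in N
  edge <- 1 / (1 + exp(-(wl - 740) / 12))   # logistic red edge over 690-790
  vis * (1 - edge) + nir * edge
}

# Bare-soil reflectance: a dim, slowly brightening line.
soil_reflectance <- function(wl) 0.12 + 2e-4 * (wl - 400)

#' Simulate one canopy reflectance spectrum
#'
#' Two-flux Beer--Lambert mixing of soil and canopy:
#' `R(lambda) = R_soil * exp(-G * LAI) + R_canopy * (1 - exp(-G * LAI))`
#' with extinction coefficient `G` (default 0.5). The canopy layer has
#' chlorophyll absorption wells in the blue (~470 nm) and red (674 nm) whose
#' depth grows with nitrogen, a green peak near 550 nm, a logistic red edge
#' over 690--790 nm and a NIR plateau that rises with nitrogen. Additive
#' Gaussian noise (default SD 0.002) is clipped so reflectance stays in
#' \[0, 1\].
#'
#' @param lai Leaf area index, must be positive.
#' @param n_rate Nitrogen rate in kg/ha, one of 0, 120, 225, 330.
#' @param seed RNG seed for the noise.
#' @param noise_sd Additive noise SD in reflectance units (default 0.002;
#'   0 gives the closed-form spectrum).
#' @param G Canopy extinction coefficient (default 0.5).
#' @param wavelengths Fine wavelength grid in nm (default 400--1000, 1 nm).
#' @return A [fine_spectrum()].
#' @export
simulate_canopy_spectrum <- function(lai, n_rate, seed = NULL,
                                     noise_sd = 0.002, G = 0.5,
                                     wavelengths = 400:1000) {
  stopifnot_scalar_number(lai, "lai")
  if (lai <= 0) stop("`lai` must be positive", call. = FALSE)
  if (!n_rate %in% N_TREATMENTS) {
    stop("`n_rate` must be one of 0, 120, 225, 330 kg/ha", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  frac <- exp(-G * lai)
  r <- soil_reflectance(wavelengths) * frac +
    canopy_layer_reflectance(wavelengths, n_rate) * (1 - frac)
  if (noise_sd > 0) {
    r <- with_seed(seed, r + stats::rnorm(length(r), 0, noise_sd))
  }
  fine_spectrum(wavelengths, pmin(pmax(r, 0), 1))
}

#' Simulate a full campaign: design, LAI, fine spectra, sensor spectra
#'
#' Convenience wrapper running [simulate_design()], [simulate_lai()] and
#' [simulate_canopy_spectrum()] per sample, then resampling every fine
#' spectrum onto the imaging grid. Flagged-unusable samples are dropped
#' before resampling (set `keep_flagged = TRUE` to keep them).
#'
#' @param n_plots Number of plots (default 44).
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param grid Imaging [band_grid()] (default [uhd_grid()]).
#' @param noise_sd Per-wavelength noise SD for the fine spectra.
#' @param sensor_noise_sd Extra per-band noise added after resampling.
#' @param keep_flagged Keep quality-flagged-out samples (default FALSE).
#' @param ... Passed to [simulate_lai()].
#' @return A list with `design`, `samples` (all generated samples incl.
#'   flags), `fines` (list of [fine_spectrum()], usable samples only unless
#'   `keep_flagged`), and `spectra` (a [spectra_set()] on `grid` with LAI).
#' @export
simulate_dataset <- function(n_plots = 44L, seed = 1L, grid = uhd_grid(),
                             noise_sd = 0.002, sensor_noise_sd = 0,
                             keep_flagged = FALSE, ...) {
  design <- simulate_design(n_plots, seed)
  samples <- simulate_lai(design, seed + 100L, ...)
  use <- if (keep_flagged) rep(TRUE, nrow(samples)) else samples$quality_flag
  used <- samples[use, , drop = FALSE]
  seeds <- with_seed(seed + 200L, sample.int(.Machine$integer.max - 1L, nrow(used)))
  fines <- lapply(seq_len(nrow(used)), function(i) {
    simulate_canopy_spectrum(used$lai[i], used$n_rate[i], seed = seeds[i],
                             noise_sd = noise_sd)
  })
  spectra <- resample_set(fines, grid,
                          metadata = used[, c("sample_id", "plot_id", "stage",
                                              "cultivar", "n_treatment",
                                              "n_rate", "area")],
                          lai = used$lai, noise_sd = sensor_noise_sd,
                          seed = seed + 300L)
  list(design = design, samples = samples, fines = fines, spectra = spectra)
}
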