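test_that("pure tones and DC land in the expected bins", {
  rate <- 128; n <- 256
  t <- seq_len(n) - 1
  x <- sin(2 * pi * 10 * t / rate)
  sp <- epoch_spectrum(x, rate)
  expect_equal(sp$freq[which.max(sp$amp[1, ])], 10)
  expect_equal(max(sp$amp[1, ]), 1, tolerance = 1e-10)
  expect_lt(sort(sp$amp[1, ], decreasing = TRUE)[2], 1e-10)
  dc <- epoch_spectrum(rep(3, n), rate)
  expect_equal(dc$amp[1, 1], 3, tolerance = 1e-10)
  expect_lt(max(dc$amp[1, -1]), 1e-10)
  expect_error(epoch_spectrum(x[1:100], rate), "epoch must be")
})

test_that("the FFT spectrum matches a naive O(N^2) DFT bin by bin", {
  set.seed(6)
  x <- rnorm(256)
  sp <- epoch_spectrum(x, 128)
  oracle <- naive_dft_amplitude(x)
  expect_equal(sp$amp[1, ], oracle, tolerance = 1e-9)
})

test_that("condition activation equals the explicit double sum", {
  set.seed(7)
  # 3 trials, one channel, 5 in-band bins: brute-force double loop oracle
  epochs <- lapply(1:3, function(i) rnorm(256, sd = 3))
  spectra <- lapply(epochs, epoch_spectrum, rate = 128)
  band <- c(8, 10)                       # 5 bins on the 0.5 Hz grid
  act <- condition_activation(spectra, band)
  sel <- which(spectra[[1]]$freq >= 8 & spectra[[1]]$freq <= 10)
  expect_length(sel, 5)
  total <- 0
  for (k in 1:3) for (nb in sel) total <- total + spectra[[k]]$amp[1, nb]
  expect_equal(unname(act), total / (3 * 5), tolerance = 1e-12)
  # constant spectra: activation equals the constant
  const <- list(structure(list(freq = spectra[[1]]$freq,
                               amp = matrix(2, 1, 129)),
                          class = "amplitude_spectrum"))
  expect_equal(unname(condition_activation(const, band)), 2)
})

test_that("relative power change reproduces the defining examples", {
  expect_equal(relative_power_change(5, 5), 0)
  expect_equal(relative_power_change((1 - 0.289) * 4, 4), -0.289)
  expect_equal(relative_power_change(8, 4), 1)     # +100% ERS
  expect_error(relative_power_change(1, 0), "positive")
})

test_that("band membership uses inclusive 0.5 Hz bin edges", {
  rate <- 128
  t <- seq_len(256) - 1
  at_13 <- epoch_spectrum(sin(2 * pi * 13 * t / rate), rate)
  at_135 <- epoch_spectrum(sin(2 * pi * 13.5 * t / rate), rate)
  alpha <- band_bins(at_13$freq, c(8, 13))
  expect_gt(sum(at_13$amp[1, alpha]), 0.9)
  expect_lt(sum(at_135$amp[1, alpha]), 1e-9)
  beta <- band_bins(at_135$freq, c(14, 30))
  expect_lt(sum(at_135$amp[1, beta]), 1e-9)  # 13.5 in neither band
  expect_error(band_bins(at_13$freq, c(8.1, 8.4)), "empty")
})

test_that("scaling all epochs leaves every power change unchanged", {
  cfg <- tiny_config(n_trials = 5, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 15)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  map1 <- erd_scalp_map(ep, "MT_HIGH", "alpha")
  ep2 <- ep; ep2$data <- ep$data * 13.7
  map2 <- erd_scalp_map(ep2, "MT_HIGH", "alpha")
  expect_equal(map1$power_change, map2$power_change, tolerance = 1e-12)
})

test_that("power-change estimates converge toward the injected fraction", {
  est <- vapply(c(10, 50), function(L) {
    cfg <- tiny_config(n_trials = L, eog_rate = 0)
    sim <- simulate_subject(cfg, seed = 500 + L)
    rec <- preprocess_recording(sim$recording, calibration = NULL)
    ep <- extract_epochs(rec)
    amps <- band_amplitudes(ep, c(8, 13))
    -relative_power_change(
      condition_activation(amps[ep$condition == "MT_HIGH", , drop = FALSE]),
      condition_activation(amps[ep$condition == "REST", , drop = FALSE]))[["C3"]]
  }, 0)
  expect_lt(abs(est[2] - 0.289), abs(est[1] - 0.289) + 0.05)
  expect_equal(est[2], 0.289, tolerance = 0.06)
})

test_that("an ERD injected at a single electrode is detected only there", {
  erd <- data.frame(condition = "MT_HIGH", band = "alpha",
                    electrode = "C3", erd = 0.5)
  cfg <- tiny_config(n_trials = 25, eog_rate = 0, erd_table = erd)
  sim <- simulate_subject(cfg, seed = 16)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  map <- erd_scalp_map(ep, "MT_HIGH", "alpha")
  expect_lt(map$p_value[map$electrode == "C3"], 1e-4)
  expect_lt(map$percent[map$electrode == "C3"], -35)
  others <- map$p_value[map$electrode != "C3" & !map$removed]
  expect_lt(sum(others < 0.01, na.rm = TRUE), 3)
})

test_that("scalp maps demand a matching-origin rest baseline", {
  cfg <- tiny_config(n_trials = 4, conditions = "MT_HIGH", eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 17)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  expect_error(erd_scalp_map(ep, "SS_LOW", "alpha"), "condition")
  no_rest <- subset_epochs(ep, ep$condition != "REST")
  expect_error(erd_scalp_map(no_rest, "MT_HIGH", "alpha"), "origin")
})
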