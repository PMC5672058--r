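test_that("filter keeps the pass band and kills the notch and stop band", {
  rec <- tone_recording(rate = 512, seconds = 4, freqs = c(10, 37.5, 50),
                        labels = c("C3", "C4", "Cz"))
  out <- filter_recording(rec)
  mid <- 513:1536                      # interior, away from edge transients
  amp_ratio <- apply(out$signal[, mid], 1, function(x) max(abs(x))) /
    apply(rec$signal[, mid], 1, function(x) max(abs(x)))
  expect_gt(amp_ratio[1], 0.95)        # 10 Hz preserved within 5%
  expect_lt(amp_ratio[2], 0.1)         # 37.5 Hz reduced >= 10x
  expect_lt(amp_ratio[3], 0.1)         # 50 Hz reduced >= 10x
})

test_that("measured impulse response matches the designed response", {
  n <- 4096
  rec <- recording(matrix(c(numeric(n / 2), 1, numeric(n / 2 - 1)), 1),
                   512, "Cz")
  out <- filter_recording(rec)
  h <- out$signal[1, ]
  measured <- Mod(stats::fft(h))[1:(n / 2 + 1)]
  f <- (0:(n / 2)) * 512 / n
  designed <- filter_response(f)
  expect_equal(measured, designed, tolerance = 1e-6)
})

test_that("designed response meets the stated tolerances", {
  f_pass <- seq(1, 35, by = 0.5)
  g_pass <- 20 * log10(filter_response(f_pass))
  expect_true(all(g_pass > -1))
  expect_lt(20 * log10(filter_response(37.5)), -20)
  f_stop <- seq(48, 256, by = 1)
  expect_true(all(20 * log10(filter_response(f_stop)) < -20))
})

test_that("filtering requires an adequate sampling rate", {
  rec <- tone_recording(rate = 64, seconds = 1, freqs = 10, labels = "Cz")
  expect_error(filter_recording(rec), "rate")
})

test_that("decimation re-indexes events and preserves tone frequency", {
  rate <- 512
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  rec <- recording(matrix(sin(2 * pi * 10 * t), 1), rate, "C3",
                   events = data.frame(sample = 512L, code = "go"))
  out <- downsample(rec, 128)
  expect_equal(out$rate, 128)
  expect_equal(ncol(out$signal), length(t) / 4)
  expect_equal(out$events$sample, 128L)
  # dominant frequency unchanged
  sp <- epoch_spectrum(out$signal[, 1:256], 128)
  expect_equal(sp$freq[which.max(sp$amp[1, ])], 10)
  expect_error(downsample(rec, 100), "divide")
})

test_that("mask decimation is conservative (exhaustive 16-sample toy)", {
  for (bad in seq_len(16)) {
    v <- matrix(TRUE, 1, 16)
    v[1, bad] <- FALSE
    rec <- recording(matrix(rnorm(16), 1), 8, "C3", validity = v)
    out <- downsample(rec, 2)
    expect_equal(ncol(out$signal), 4)
    expect_equal(which(!out$validity[1, ]), ceiling(bad / 4))
  }
})

test_that("a spike is masked with padding, exactly where expected", {
  rate <- 128
  x <- rnorm(rate * 10, sd = 1)
  spike_at <- 600:609
  x[spike_at] <- 500
  rec <- recording(matrix(x, 1), rate, "C3")
  out <- mask_artifacts(rec, amplitude_threshold = 100, diff_threshold = 1e9,
                        pad_s = 0.2)
  pad <- round(0.2 * rate)
  # brute-force oracle: threshold scan plus dilation
  bad <- abs(x) > 100
  expected <- rep(FALSE, length(x))
  for (i in which(bad)) {
    expected[max(1, i - pad):min(length(x), i + pad)] <- TRUE
  }
  expect_equal(which(!out$validity[1, ]), which(expected))
})

test_that("a channel saturated over half the time is excluded", {
  rate <- 128
  n <- rate * 10
  sig <- rbind(rnorm(n), rnorm(n))
  sig[2, 1:(0.6 * n)] <- 150
  rec <- recording(sig, rate, c("C3", "F6"))
  out <- mask_artifacts(rec)
  expect_identical(out$excluded, "F6")
  expect_false("C3" %in% out$excluded)
})

test_that("clean simulated data is not masked at default thresholds", {
  cfg <- tiny_config(n_trials = 2, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 33)
  rec <- downsample(filter_recording(sim$recording), 128)
  out <- mask_artifacts(rec)
  expect_equal(sum(attr(out, "mask_report")$new_invalid), 0)
})

test_that("common average reference matches manual column-mean subtraction", {
  # already zero-mean pair is unchanged
  a <- rnorm(50)
  rec <- recording(rbind(a, -a), 128, c("C3", "C4"))
  expect_equal(common_average_reference(rec)$signal, rec$signal,
               ignore_attr = TRUE)
  # constant offset across channels becomes zero
  rec2 <- recording(matrix(7, 4, 10), 128, c("C3", "C4", "Cz", "Pz"))
  expect_true(all(common_average_reference(rec2)$signal == 0))
  # random matrix equals brute-force subtraction
  m <- matrix(rnorm(16), 4)
  rec3 <- recording(m, 128, c("C3", "C4", "Cz", "Pz"))
  manual <- m
  for (j in 1:4) manual[, j] <- m[, j] - mean(m[, j])
  expect_equal(common_average_reference(rec3)$signal, manual,
               ignore_attr = TRUE)
})

test_that("CAR is idempotent and leaves excluded channels untouched", {
  m <- matrix(rnorm(40), 4)
  rec <- recording(m, 128, c("C3", "C4", "Cz", "Pz"), excluded = "Pz")
  once <- common_average_reference(rec)
  twice <- common_average_reference(once)
  expect_equal(once$signal, twice$signal)
  expect_equal(once$signal["Pz", ], m[4, ], ignore_attr = TRUE)
  rec_all <- recording(m, 128, c("C3", "C4", "Cz", "Pz"),
                       excluded = c("C3", "C4", "Cz", "Pz"))
  expect_error(common_average_reference(rec_all), "two")
})

test_that("ocular subtraction is near-identity without ocular activity", {
  cfg <- tiny_config(n_trials = 2, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 8)
  model <- fit_eog(sim$calibration)
  rec <- sim$recording
  corrected <- apply_eog(rec, model)
  rel <- sqrt(sum((corrected$signal - rec$signal)^2) / sum(rec$signal^2))
  expect_lt(rel, 0.05)
})

test_that("known injected ocular activity is removed against ground truth", {
  cfg <- tiny_config(n_trials = 3, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 9)
  clean <- sim$recording
  tpl <- default_eog_template(clean$rate, standard_layout(), "blink", 80, 0.3)
  dirty <- inject_eog(clean, rate_per_min = 12, tpl, seed = 10)
  expect_gt(nrow(dirty$log), 0)
  model <- fit_eog(sim$calibration)
  corrected <- apply_eog(dirty$recording, model)
  err_dirty <- sqrt(mean((dirty$recording$signal - clean$signal)^2))
  err_corr <- sqrt(mean((corrected$signal - clean$signal)^2))
  rel <- sqrt(sum((corrected$signal - clean$signal)^2) / sum(clean$signal^2))
  expect_lt(rel, 0.05)                 # within 5% RMS of the clean copy
  expect_lt(err_corr, 0.3 * err_dirty) # most artifact energy removed
})

test_that("channels outside the artifact subspace stay unchanged", {
  # synthetic model with an exactly zero coefficient for a posterior channel
  set.seed(14)
  labs <- c("Fp1", "Fp2", "AF3", "AF4", "Pz")
  n <- 2000
  art <- sin(2 * pi * 0.8 * seq_len(n) / 256)^2
  prof <- c(1, 0.9, 0.6, 0.55, 0)
  calib <- recording(outer(prof, art) * 80 + matrix(rnorm(5 * n), 5), 256, labs)
  model <- fit_eog(calib, n_sources = 1, frontal = labs[1:4])
  expect_lt(abs(model$coefficients[5, 1]) / abs(model$coefficients[1, 1]), 0.05)
  rec <- recording(matrix(rnorm(5 * 512), 5), 256, labs)
  corrected <- apply_eog(rec, model)
  expect_equal(corrected$signal[5, ], rec$signal[5, ],
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("calibration preconditions are enforced", {
  short <- recording(matrix(rnorm(64), 8), 128,
                     c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "Cz", "Pz"))
  expect_error(fit_eog(short), "too short")
})
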