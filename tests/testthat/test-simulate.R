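test_that("identical config and seed give bit-identical recordings", {
  cfg <- tiny_config(n_trials = 2)
  a <- simulate_subject(cfg, seed = 99)
  b <- simulate_subject(cfg, seed = 99)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$trials, b$trials)
  expect_identical(a$calibration$signal, b$calibration$signal)
  c <- simulate_subject(cfg, seed = 100)
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(rate = 50), "twice")
  bad_erd <- default_erd_table(); bad_erd$erd[1] <- 1.2
  expect_error(simulation_config(erd_table = bad_erd), "\\[0, 1\\)")
  bad_el <- default_erd_table(); bad_el$electrode[1] <- "XX9"
  expect_error(simulation_config(erd_table = bad_el), "absent")
  expect_error(simulation_config(conditions = "MT_MEDIUM"), "unknown")
})

test_that("rest background follows the configured 1/f exponent", {
  cfg <- tiny_config(n_trials = 3, conditions = character(0), eog_rate = 0)
  cfg$baseline$alpha[] <- 0            # no oscillations: pure background
  cfg$baseline$beta[] <- 0
  sim <- simulate_subject(cfg, seed = 5)
  x <- sim$recording$signal
  n_ep <- ncol(x) %/% 256
  pows <- 0
  for (i in seq_len(n_ep)) {
    sp <- epoch_spectrum(x[1:8, ((i - 1) * 256 + 1):(i * 256)], 128)
    pows <- pows + colMeans(sp$amp^2)
  }
  f <- sp$freq
  sel <- f >= 2 & f <= 40
  fit <- stats::lm(log(pows[sel]) ~ log(f[sel]))
  expect_equal(unname(stats::coef(fit)[2]), -cfg$noise$exponent,
               tolerance = 0.15)
})

test_that("larger injected ERD yields monotonically larger measured ERD", {
  measure <- function(d, seed) {
    erd <- data.frame(condition = "MT_HIGH", band = "alpha",
                      electrode = "C3", erd = d)
    cfg <- tiny_config(n_trials = 18, eog_rate = 0, erd_table = erd)
    sim <- simulate_subject(cfg, seed = seed)
    rec <- preprocess_recording(sim$recording, calibration = NULL)
    ep <- extract_epochs(rec)
    amps <- band_amplitudes(ep, c(8, 13))
    pc <- relative_power_change(
      condition_activation(amps[ep$condition == "MT_HIGH", , drop = FALSE]),
      condition_activation(amps[ep$condition == "REST", , drop = FALSE]))
    -pc[["C3"]]
  }
  grid <- c(0.05, 0.25, 0.45, 0.65)
  est <- vapply(seq_along(grid), function(i) measure(grid[i], 40 + i), 0)
  expect_equal(cor(est, grid, method = "spearman"), 1)
})

test_that("zero injected ERD leaves condition and rest amplitudes equal", {
  erd <- default_erd_table(); erd$erd[] <- 0
  cfg <- tiny_config(n_trials = 15, eog_rate = 0, erd_table = erd)
  sim <- simulate_subject(cfg, seed = 77)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  amps <- band_amplitudes(ep, c(8, 13))
  pc <- relative_power_change(
    condition_activation(amps[ep$condition == "MT_HIGH", , drop = FALSE]),
    condition_activation(amps[ep$condition == "REST", , drop = FALSE]))
  expect_lt(max(abs(pc)), 0.2)         # within sampling noise at n = 15
  expect_lt(abs(mean(pc)), 0.05)
})

test_that("the envelope-gain solver hits the requested measured ratio", {
  cfg <- tiny_config()
  expected <- mucross:::make_expected_amplitude(cfg, c(8, 13))
  for (d in c(0.1, 0.289, 0.6)) {
    g <- mucross:::solve_envelope_gain(expected, 5, 2.5, d, "alpha")
    ratio <- expected(5, 2.5, g, 1) / expected(5, 2.5, 1, 1)
    expect_equal(ratio, 1 - d, tolerance = 1e-4)
  }
  # unreachable ERD (background noise floor) errors
  expect_error(
    mucross:::solve_envelope_gain(expected, 0.3, 0.1, 0.9, "alpha"),
    "unreachable")
})

test_that("ocular injection respects rate zero and the spatial profile", {
  cfg <- tiny_config(n_trials = 2, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 3)
  tpl <- default_eog_template(128, standard_layout(), "blink", 80, 0.3)
  none <- inject_eog(sim$recording, 0, tpl)
  expect_identical(none$recording$signal, sim$recording$signal)
  expect_equal(nrow(none$log), 0)
  many <- inject_eog(sim$recording, 30, tpl, seed = 4)
  v_ratio <- apply(many$recording$signal, 1, var) /
    apply(sim$recording$signal, 1, var)
  names(v_ratio) <- sim$recording$labels
  expect_gt(v_ratio[["Fp1"]], 1.5)         # frontal variance rises
  expect_lt(abs(v_ratio[["Pz"]] - 1), 0.05) # Pz nearly unchanged
})

test_that("force traces meet or violate the success criterion by design", {
  cfg <- simulation_config()
  set.seed(2)
  ok <- simulate_force("MT_LOW", cfg, success_target = TRUE)
  expect_true(evaluate_trial_success(ok, "MT_LOW", cfg))
  bad <- simulate_force("MT_HIGH", cfg, success_target = FALSE)
  expect_false(evaluate_trial_success(bad, "MT_HIGH", cfg))
  expect_error(simulate_force("REST", cfg), "motor")
  # mean in-band force of a successful low-force trial: 2.5 N +/- 20%
  act <- (attr(ok, "action_start") + 1):ncol(ok)
  m <- mean(colMeans(ok[, act]))
  expect_gte(m, 2.0)
  expect_lte(m, 3.0)
  expect_true(all(ok >= 0))
})
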