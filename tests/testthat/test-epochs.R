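flat_force <- function(value, cfg, rate = 128, fingers = 5) {
  n_orient <- round(cfg$timing$orientation * rate)
  n_action <- round(cfg$timing$action * rate)
  structure(matrix(value, fingers, n_orient + n_action), rate = rate,
            action_start = n_orient, class = c("force_trace", "matrix"))
}

test_that("constant target force succeeds, zero force fails", {
  cfg <- simulation_config()
  expect_true(evaluate_trial_success(flat_force(2.5, cfg), "MT_LOW", cfg))
  expect_true(evaluate_trial_success(flat_force(6.5, cfg), "MT_HIGH", cfg))
  expect_false(evaluate_trial_success(flat_force(0, cfg), "MT_LOW", cfg))
  # interval edges: 2.5 N +/- 20% -> [2.0, 3.0]
  expect_true(evaluate_trial_success(flat_force(2.0, cfg), "MT_LOW", cfg))
  expect_false(evaluate_trial_success(flat_force(1.99, cfg), "MT_LOW", cfg))
})

test_that("the 80% criterion is a >= comparison on discrete samples", {
  cfg <- simulation_config()
  rate <- 128
  n_action <- round(cfg$timing$action * rate)   # 384 samples
  make <- function(n_good) {
    f <- flat_force(2.5, cfg, rate)
    act0 <- attr(f, "action_start")
    if (n_good < n_action) {
      f[, (act0 + n_good + 1):(act0 + n_action)] <- 0
    }
    f
  }
  k80 <- ceiling(0.8 * n_action)
  expect_true(evaluate_trial_success(make(k80), "MT_LOW", cfg))       # exactly 80%
  expect_false(evaluate_trial_success(make(k80 - 4), "MT_LOW", cfg))  # ~79%
})

test_that("per-finger strict evaluation differs from the mean-force reading", {
  cfg <- simulation_config()
  f <- flat_force(2.5, cfg)
  f[1, ] <- 4.0; f[2, ] <- 1.0          # mean still 2.5 per sample
  expect_true(evaluate_trial_success(f, "MT_LOW", cfg))
  expect_false(evaluate_trial_success(f, "MT_LOW", cfg,
                                      per_finger_strict = TRUE))
})

test_that("short traces and non-motor trials are rejected", {
  cfg <- simulation_config()
  f <- flat_force(2.5, cfg)
  expect_error(evaluate_trial_success(f[, 1:100], "MT_LOW", cfg, rate = 128,
                                      action_start = attr(f, "action_start")),
               "shorter")
  expect_error(evaluate_trial_success(f, "SS_LOW", cfg), "motor")
})

test_that("epoch windows are [onset + 0.5 s, onset + 2.5 s) at 128 Hz", {
  n <- 128 * 30
  ev <- data.frame(sample = 1280L, code = "action_start",
                   condition = "MT_LOW", block = 1L, trial = 1L,
                   success = TRUE)
  sig <- matrix(seq_len(n), 1)          # signal value = sample index + 1
  rec <- recording(sig, 128, "C3", events = ev)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(1, 256, 1))
  # 0-based samples [1344, 1600) -> values 1345..1600
  expect_equal(ep$data[1, 1, 1], 1345)
  expect_equal(ep$data[1, 256, 1], 1600)
})

test_that("failed trials are omitted and counts match successes", {
  cfg <- tiny_config(n_trials = 6, conditions = c("MT_LOW", "MT_HIGH"),
                     eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 12)
  expect_gt(sum(!sim$trials$success), 0)   # some failed attempts exist
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  counts <- epoch_counts(ep)
  expect_equal(unname(counts["MT_LOW"]), 6)
  expect_equal(unname(counts["MT_HIGH"]), 6)
  expect_equal(unname(counts["REST"]), 6)
  failed <- sim$trials$trial[!sim$trials$success]
  expect_false(any(failed %in% ep$trial))
})

test_that("rest epochs carry their block-type origin", {
  cfg <- tiny_config(n_trials = 3, conditions = c("MT_LOW", "SS_LOW"),
                     eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 13)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  rest_origin <- ep$origin[ep$condition == "REST"]
  expect_setequal(unique(rest_origin), c("MT", "SS"))
  expect_equal(sum(rest_origin == "MT"), 3)
  expect_equal(sum(rest_origin == "SS"), 3)
})

test_that("windows beyond the recording bounds are an error", {
  ev <- data.frame(sample = 100L, code = "action_start",
                   condition = "MT_LOW", block = 1L, trial = 1L, success = TRUE)
  rec <- recording(matrix(rnorm(200), 1), 128, "C3", events = ev)
  expect_error(extract_epochs(rec), "bounds")
  rec2 <- recording(matrix(rnorm(200), 1), 128, "C3")
  expect_error(extract_epochs(rec2), "marker")
})
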