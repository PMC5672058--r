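# Synthetic-subject generator.
#
# One synthetic subject is a continuous 64-channel recording composed of
# 1/f background noise, band-limited mu (alpha) and beta oscillations with
# electrode-specific baseline amplitudes (including an occipital alpha
# excess), transient ocular artifacts, and grip-force traces for motor
# trials.  Within the action phase of each non-rest trial the oscillation
# envelope at each electrode is scaled such that the *expected measured*
# band amplitude (FFT magnitude averaged over band bins after the full
# preprocessing chain, i.e. oscillation plus in-band noise) equals
# (1 - erd) times its rest-trial expectation.  This makes the injected ERD
# fractions recoverable in expectation by the analysis chain.

CONDITIONS <- c("MT_LOW", "MT_HIGH", "SS_LOW", "SS_HIGH", "REST")

#' Published-magnitude ERD parameter table
#'
#' Fractional band-amplitude decreases (relative to rest) at the six
#' sensorimotor electrodes for the four experimental conditions, alpha and
#' beta bands.  These are the generator defaults and define the synthetic
#' study's effect sizes.
#'
#' @return Data frame with columns `condition`, `band`, `electrode`, `erd`
#'   (fraction in `[0, 1)`).
#' @export
default_erd_table <- function() {
  electrodes <- c("C3", "CP3", "FC3", "C4", "CP4", "FC4")
  alpha <- rbind(
    MT_LOW  = c(23.8, 17.8, 11.9, 18.1, 13.7, 10.6),
    MT_HIGH = c(28.9, 24.6, 14.3, 26.9, 21.0, 15.5),
    SS_LOW  = c(17.2, 14.0,  9.4, 12.3, 10.3,  5.6),
    SS_HIGH = c(18.6, 14.5, 10.9, 12.6,  9.9,  6.8))
  beta <- rbind(
    MT_LOW  = c( 8.5,  6.0,  4.1,  5.2,  6.0,  5.9),
    MT_HIGH = c(13.7, 11.0,  6.6, 11.5,  9.0,  9.6),
    SS_LOW  = c( 7.4,  7.3,  4.2,  4.5,  5.0,  2.0),
    SS_HIGH = c( 8.7,  7.1,  4.6,  5.0,  5.2,  1.2))
  build <- function(m, band) {
    data.frame(condition = rep(rownames(m), each = ncol(m)),
               band = band,
               electrode = rep(electrodes, times = nrow(m)),
               erd = as.vector(t(m)) / 100,
               stringsAsFactors = FALSE)
  }
  rbind(build(alpha, "alpha"), build(beta, "beta"))
}

#' Default per-electrode baseline rhythm amplitudes
#'
#' Rest-state RMS amplitudes (microvolts, arbitrary but realistic units) of
#' the band-limited alpha and beta components per electrode: a moderate mu
#' rhythm over the scalp, an occipital alpha excess, reduced alpha
#' frontally.
#'
#' @param layout An `electrode_layout`.
#' @return Data frame with columns `electrode`, `alpha`, `beta`.
#' @export
default_baseline_amplitudes <- function(layout = standard_layout()) {
  labs <- layout$names
  alpha <- rep(5, length(labs))
  alpha[grepl("^(O|PO|I)", labs)] <- 7
  alpha[grepl("^(Fp|AF)", labs)] <- 3
  beta <- rep(1.5, length(labs))
  beta[labs %in% feature_electrodes()] <- 2.5
  data.frame(electrode = labs, alpha = alpha, beta = beta,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every generator parameter.  The defaults encode the emulated
#' study conditions: 64-channel 10-10 montage at 512 Hz, 50 successful
#' trials per condition plus 50 rest trials per block type, trial phases
#' cue 0.3 s / break 2-4 s (2 s in stimulation blocks) / orientation 2.5 s /
#' action 3 s / inter-trial 3 s, and the published ERD magnitudes.
#'
#' @param montage Montage id (see [standard_layout()]).
#' @param rate Sampling rate, Hz; must exceed twice the highest synthesized
#'   frequency (beta upper edge, 30 Hz).
#' @param n_trials Successful trials per experimental condition.
#' @param n_rest Rest trials per block type (defaults to `n_trials`).
#' @param conditions Experimental conditions to simulate.
#' @param timing Trial phase durations in seconds.
#' @param erd_table Data frame (condition, band, electrode, erd fraction).
#' @param baseline Per-electrode baseline amplitudes, see
#'   [default_baseline_amplitudes()].
#' @param noise 1/f background model: `exponent`, `scale` (amplitude
#'   spectral density in microvolts/sqrt(Hz) at `ref` Hz), `floor`
#'   (flattening frequency, Hz).
#' @param bands Oscillation band edges (Hz) and Butterworth shape order.
#' @param trial_var Trial-to-trial lognormal variability of the oscillation
#'   envelope: `global_sd` (shared across electrodes) and `channel_sd`
#'   (independent per electrode), both on the log scale.
#' @param eog Ocular-artifact model: blink `rate_per_min`, peak `amplitude`
#'   (microvolts at the most frontal row), spatial `decay` (units of head
#'   radius in the anterior-posterior direction).
#' @param force Grip-force model: targets (N per finger), relative
#'   tolerances, number of fingers.
#' @param success_rate Probability that an attempted motor trial succeeds;
#'   failed attempts are re-queued so `n_trials` successes are reached.
#' @param subject_gain Per-subject multiplicative gain on all ERD fractions:
#'   `mean`, `sd`, `min` (truncation) — or `fixed` to pin the gain (0
#'   reproduces a subject without usable mu modulation).
#' @param blocks_per_type Number of blocks per block type.
#' @param seed Default RNG seed used by [simulate_subject()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(montage = "10-10-64",
                              rate = 512,
                              n_trials = 50,
                              n_rest = n_trials,
                              conditions = c("MT_LOW", "MT_HIGH",
                                             "SS_LOW", "SS_HIGH"),
                              timing = list(cue = 0.3, break_range = c(2, 4),
                                            break_ss = 2, orientation = 2.5,
                                            action = 3, iti = 3),
                              erd_table = default_erd_table(),
                              baseline = default_baseline_amplitudes(),
                              noise = list(exponent = 1.2, scale = 0.55,
                                           ref = 10, floor = 0.5),
                              bands = list(alpha = c(8, 13), beta = c(14, 30),
                                           order = 4),
                              trial_var = list(global_sd = 0.20,
                                               channel_sd = 0.10),
                              eog = list(rate_per_min = 10, amplitude = 80,
                                         decay = 0.3),
                              force = list(target = c(MT_LOW = 2.5,
                                                      MT_HIGH = 6.5),
                                           tolerance = c(MT_LOW = 0.2,
                                                         MT_HIGH = 0.1),
                                           n_fingers = 5),
                              success_rate = c(MT_LOW = 0.864, MT_HIGH = 0.816),
                              subject_gain = list(mean = 1, sd = 0.15,
                                                  min = 0.5, fixed = NULL),
                              blocks_per_type = 3,
                              seed = 1) {
  cfg <- list(montage = montage, rate = rate, n_trials = n_trials,
              n_rest = n_rest, conditions = conditions, timing = timing,
              erd_table = erd_table, baseline = baseline, noise = noise,
              bands = bands, trial_var = trial_var, eog = eog, force = force,
              success_rate = success_rate, subject_gain = subject_gain,
              blocks_per_type = blocks_per_type, seed = seed)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 1, cfg$n_rest >= 0)
  if (cfg$rate <= 2 * max(cfg$bands$beta)) {
    stop("rate must exceed twice the highest synthesized frequency",
         call. = FALSE)
  }
  if (any(cfg$erd_table$erd < 0 | cfg$erd_table$erd >= 1)) {
    stop("erd fractions must lie in [0, 1)", call. = FALSE)
  }
  bad <- setdiff(cfg$conditions, setdiff(CONDITIONS, "REST"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  layout <- standard_layout(cfg$montage)
  missing <- setdiff(cfg$erd_table$electrode, layout$names)
  if (length(missing)) {
    stop("erd_table electrode(s) absent from montage: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Spectral model shared by the synthesizer and the envelope-gain solver.

# Butterworth band-pass power response (unit peak).
band_shape <- function(f, edges, order) {
  f0sq <- edges[1] * edges[2]
  bw <- edges[2] - edges[1]
  omega <- (f^2 - f0sq) / pmax(abs(f) * bw, 1e-12)
  1 / (1 + omega^(2 * order))
}

# Band shape normalized to unit total power (one-sided PSD of a
# unit-variance oscillation process), evaluated at `f`.
unit_band_psd <- function(f, edges, order, rate) {
  grid <- seq(0, rate / 2, by = 0.01)
  norm <- sum(band_shape(grid, edges, order)) * 0.01
  band_shape(f, edges, order) / norm
}

# One-sided 1/f background PSD in (microvolt)^2/Hz.
noise_psd <- function(f, noise) {
  fx <- pmax(abs(f), noise$floor)
  noise$scale^2 * (noise$ref / fx)^noise$exponent
}

# Expected per-bin smoothing of a 2-s rectangular analysis window: the
# periodogram expectation is the PSD convolved with the Fejer kernel.
# Returns a matrix bins x fine-grid applying that convolution.
fejer_smoother <- function(bin_freqs, fine, T = 2) {
  df <- fine[2] - fine[1]
  K <- outer(bin_freqs, fine, function(fk, fp) {
    x <- (fk - fp) * T
    w <- ifelse(abs(x) < 1e-9, 1, (sin(pi * x) / (pi * x))^2)
    # negative-frequency image of the kernel
    x2 <- (fk + fp) * T
    w2 <- ifelse(abs(x2) < 1e-9, 1, (sin(pi * x2) / (pi * x2))^2)
    (w + w2) * T
  })
  K * df
}

# Internal: per-channel expected band amplitude machinery at the analysis
# stage (128 Hz, 2-s rectangular window), including the preprocessing filter
# response and trial-to-trial lognormal envelope variability.
make_expected_amplitude <- function(cfg, band_edges, analysis_rate = 128) {
  fine <- seq(0, analysis_rate / 2, by = 0.05)
  bin_f <- seq(0, analysis_rate / 2, by = 0.5)
  in_band <- bin_f >= band_edges[1] & bin_f <= band_edges[2]
  bins <- bin_f[in_band]
  K <- fejer_smoother(bins, fine)
  H2 <- filter_response(fine)^2
  shape_a <- unit_band_psd(fine, cfg$bands$alpha, cfg$bands$order, cfg$rate)
  shape_b <- unit_band_psd(fine, cfg$bands$beta, cfg$bands$order, cfg$rate)
  pn <- noise_psd(fine, cfg$noise)
  sm_a <- drop(K %*% (H2 * shape_a))
  sm_b <- drop(K %*% (H2 * shape_b))
  sm_n <- drop(K %*% (H2 * pn))
  sd_l <- sqrt(cfg$trial_var$global_sd^2 + cfg$trial_var$channel_sd^2)
  m <- 40
  Lq <- stats::qlnorm((seq_len(m) - 0.5) / m, meanlog = 0, sdlog = sd_l)
  # E over trials of the mean band-bin amplitude for alpha gain ga, beta gain gb
  function(amp_a, amp_b, ga = 1, gb = 1) {
    tot <- outer(Lq^2, (ga * amp_a)^2 * sm_a + (gb * amp_b)^2 * sm_b)
    tot <- sweep(tot, 2, sm_n, "+")
    mean(rowMeans(sqrt(tot)))
  }
}

# Solve for the envelope gain that achieves the target measured-amplitude
# ratio (1 - erd) in expectation.  Monotone in g, so uniroot on [0, 1].
solve_envelope_gain <- function(expected, amp_a, amp_b, erd, band,
                                other_gain = 1) {
  if (erd <= 0) return(1)
  if (band == "alpha") {
    rest <- expected(amp_a, amp_b, 1, other_gain)
    f <- function(g) expected(amp_a, amp_b, g, other_gain) - (1 - erd) * rest
  } else {
    rest <- expected(amp_a, amp_b, other_gain, 1)
    f <- function(g) expected(amp_a, amp_b, other_gain, g) - (1 - erd) * rest
  }
  if (f(0) > 0) {
    stop(sprintf("requested erd %.3f unreachable: in-band background noise %s",
                 erd, "exceeds the target amplitude"), call. = FALSE)
  }
  stats::uniroot(f, c(0, 1), tol = 1e-6)$root
}

# ---------------------------------------------------------------------------
# Trial sequencing

# Build the trial table for one subject: condition, block, phase onsets.
build_trial_table <- function(cfg) {
  block_types <- unique(substr(cfg$conditions, 1, 2))
  if (!length(block_types)) block_types <- "MT"
  rows <- list()
  for (bt in block_types) {
    conds <- cfg$conditions[substr(cfg$conditions, 1, 2) == bt]
    for (cond in conds) {
      n_succ <- cfg$n_trials
      sr <- if (cond %in% names(cfg$success_rate)) cfg$success_rate[[cond]] else 1
      n_fail <- round(n_succ * (1 - sr) / sr)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, block_type = bt,
        success = rep(c(TRUE, FALSE), c(n_succ, n_fail)))
    }
    if (cfg$n_rest > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = "REST", block_type = bt,
        success = TRUE)[rep(1, cfg$n_rest), ]
    }
  }
  tab <- do.call(rbind, rows)
  # distribute each block type's trials over its blocks and shuffle within
  out <- list()
  block_id <- 0L
  for (bt in unique(tab$block_type)) {
    sub <- tab[tab$block_type == bt, ]
    sub <- sub[sample.int(nrow(sub)), ]
    splits <- sort(rep_len(seq_len(cfg$blocks_per_type), nrow(sub)))
    for (b in seq_len(cfg$blocks_per_type)) {
      block_id <- block_id + 1L
      chunk <- sub[splits == b, ]
      chunk$block <- block_id
      out[[length(out) + 1L]] <- chunk
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$trial <- seq_len(nrow(tab))
  tab
}

# Add phase onset samples (0-based) to a trial table.
add_trial_timing <- function(tab, cfg) {
  rate <- cfg$rate
  tm <- cfg$timing
  lead <- 2
  t0 <- lead
  n <- nrow(tab)
  cue_on <- go_on <- action_on <- action_off <- t_end <- numeric(n)
  brk <- ifelse(tab$block_type == "MT",
                stats::runif(n, tm$break_range[1], tm$break_range[2]),
                tm$break_ss)
  for (i in seq_len(n)) {
    cue_on[i] <- t0
    go_on[i] <- cue_on[i] + tm$cue + brk[i]
    action_on[i] <- go_on[i] + tm$orientation
    action_off[i] <- action_on[i] + tm$action
    t_end[i] <- action_off[i] + tm$iti
    t0 <- t_end[i]
  }
  tab$cue_sample <- sec_to_sample(cue_on, rate)
  tab$go_sample <- sec_to_sample(go_on, rate)
  tab$action_sample <- sec_to_sample(action_on, rate)
  tab$action_end_sample <- sec_to_sample(action_off, rate)
  tab$end_sample <- sec_to_sample(t_end, rate)
  attr(tab, "total_seconds") <- t0 + 2
  tab
}

trial_events <- function(tab) {
  ev <- function(code, col) {
    data.frame(sample = tab[[col]], code = code, condition = tab$condition,
               origin = tab$block_type, block = tab$block, trial = tab$trial,
               success = tab$success, stringsAsFactors = FALSE)
  }
  rbind(ev("cue", "cue_sample"), ev("go", "go_sample"),
        ev("action_start", "action_sample"),
        ev("action_end", "action_end_sample"))
}

# ---------------------------------------------------------------------------
# Signal synthesis

# Two independent shaped-noise channels per FFT: synthesize a complex
# spectrum without Hermitian symmetry; the real and imaginary parts of its
# inverse FFT are independent Gaussian processes with one-sided PSD
# `psd_vals` (given on the full FFT frequency grid, length n).
shaped_noise_pair <- function(n, rate, psd_vals) {
  amp <- sqrt(n * rate * psd_vals / 2)
  X <- amp * complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  stats::fft(X, inverse = TRUE) / n
}

# Moving-average smoothing (O(n) via cumulative sums); turns the piecewise-
# constant trial envelopes into short ramps so the synthesized rhythms stay
# band-limited.
smooth_envelope <- function(env, w) {
  if (w <= 1) return(env)
  n <- length(env)
  cs <- cumsum(c(0, env))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate one synthetic subject
#'
#' Generates the continuous EEG recording, grip-force traces for motor
#' trials, an ocular-calibration recording and the ground-truth tables for
#' one subject under a [simulation_config()].  Deterministic given
#' `(config, seed)`.
#'
#' @param cfg A `simulation_config`.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A list of class `simulated_subject` with elements `recording`,
#'   `force` (named list of per-trial force matrices), `calibration`,
#'   `trials` (trial table), and `truth` (subject gain, effective ERD table
#'   with solved envelope gains, ocular injection log).
#' @export
simulate_subject <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  layout <- standard_layout(cfg$montage)
  labs <- layout$names
  n_ch <- length(labs)
  rate <- cfg$rate

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)

  # subject gain on ERD fractions
  sg <- cfg$subject_gain
  gain <- if (!is.null(sg$fixed)) sg$fixed else {
    max(sg$min, stats::rnorm(1, sg$mean, sg$sd))
  }

  tab <- build_trial_table(cfg)
  tab <- add_trial_timing(tab, cfg)
  n_sec <- attr(tab, "total_seconds")
  n_data <- as.integer(ceiling(n_sec * rate))
  n_full <- stats::nextn(n_data, c(2, 3, 5))

  # frequency grid of the synthesis FFT
  k <- seq_len(n_full) - 1L
  f_grid <- pmin(k, n_full - k) * rate / n_full
  psd_n <- noise_psd(f_grid, cfg$noise)
  psd_a <- unit_band_psd(f_grid, cfg$bands$alpha, cfg$bands$order, rate)
  psd_b <- unit_band_psd(f_grid, cfg$bands$beta, cfg$bands$order, rate)

  # effective ERD per electrode/band/condition and solved envelope gains
  erd_eff <- cfg$erd_table[cfg$erd_table$condition %in% cfg$conditions, ,
                           drop = FALSE]
  erd_eff$erd <- pmin(pmax(erd_eff$erd * gain, 0), 0.95)
  base <- cfg$baseline[match(labs, cfg$baseline$electrode), ]
  exp_alpha <- make_expected_amplitude(cfg, cfg$bands$alpha)
  exp_beta <- make_expected_amplitude(cfg, cfg$bands$beta)
  erd_eff$gain_factor <- rep(1, nrow(erd_eff))
  for (i in seq_len(nrow(erd_eff))) {
    ch <- match(erd_eff$electrode[i], labs)
    expected <- if (erd_eff$band[i] == "alpha") exp_alpha else exp_beta
    erd_eff$gain_factor[i] <- solve_envelope_gain(
      expected, base$alpha[ch], base$beta[ch], erd_eff$erd[i], erd_eff$band[i])
  }

  # per-trial lognormal envelope factors (global x channel)
  n_tr <- nrow(tab)
  eta <- stats::rnorm(n_tr, 0, cfg$trial_var$global_sd)
  xi <- matrix(stats::rnorm(n_tr * n_ch, 0, cfg$trial_var$channel_sd),
               n_tr, n_ch)
  L <- exp(eta + xi)                      # trials x channels

  gain_of <- function(ch_lab, band, cond) {
    hit <- which(erd_eff$electrode == ch_lab & erd_eff$band == band &
                   erd_eff$condition == cond)
    if (length(hit)) erd_eff$gain_factor[hit[1]] else 1
  }

  w_smooth <- as.integer(round(0.25 * rate))
  build_env <- function(ch, band) {
    env <- rep(1, n_data)
    for (t in seq_len(n_tr)) {
      span <- (tab$cue_sample[t] + 1L):min(tab$end_sample[t], n_data)
      env[span] <- L[t, ch]
      if (tab$condition[t] != "REST") {
        act <- (tab$action_sample[t] + 1L):min(tab$action_end_sample[t], n_data)
        env[act] <- L[t, ch] * gain_of(labs[ch], band, tab$condition[t])
      }
    }
    smooth_envelope(env, w_smooth)
  }
  signal <- matrix(0, n_ch, n_data)
  sel <- seq_len(n_data)
  for (ch in seq(1L, n_ch, by = 2L)) {
    zn <- shaped_noise_pair(n_full, rate, psd_n)
    za <- shaped_noise_pair(n_full, rate, psd_a)
    zb <- shaped_noise_pair(n_full, rate, psd_b)
    for (off in 0:1) {
      ch2 <- ch + off
      if (ch2 > n_ch) break
      part <- if (off == 0) Re else Im
      signal[ch2, ] <- part(zn)[sel] +
        base$alpha[ch2] * build_env(ch2, "alpha") * part(za)[sel] +
        base$beta[ch2] * build_env(ch2, "beta") * part(zb)[sel]
    }
  }

  rec <- recording(signal, rate, labs, events = trial_events(tab))

  # ocular artifacts: blinks plus occasional horizontal saccades
  eog_log <- NULL
  if (cfg$eog$rate_per_min > 0) {
    blink <- inject_eog(rec, cfg$eog$rate_per_min,
                        default_eog_template(rate, layout, "blink",
                                             cfg$eog$amplitude, cfg$eog$decay))
    rec <- blink$recording
    sacc <- inject_eog(rec, cfg$eog$rate_per_min / 3,
                       default_eog_template(rate, layout, "horizontal",
                                            cfg$eog$amplitude * 0.6,
                                            cfg$eog$decay))
    rec <- sacc$recording
    eog_log <- rbind(cbind(kind = "blink", blink$log),
                     cbind(kind = "horizontal", sacc$log))
  }

  # grip-force traces for motor trials
  force <- list()
  for (t in which(substr(tab$condition, 1, 2) == "MT")) {
    force[[as.character(tab$trial[t])]] <-
      simulate_force(tab$condition[t], cfg, success_target = tab$success[t])
  }

  calibration <- simulate_calibration(cfg, layout)

  structure(list(
    recording = rec, force = force, calibration = calibration,
    trials = tab,
    truth = list(gain = gain, erd_effective = erd_eff, eog_log = eog_log,
                 seed = seed)),
    class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat(sprintf("<simulated_subject> gain %.2f, %d trials, %.0f s recording\n",
              x$truth$gain, nrow(x$trials),
              n_samples(x$recording) / x$recording$rate))
  invisible(x)
}

#' Ocular artifact template
#'
#' Waveform plus frontal spatial profile for transient ocular artifacts.
#' Blink and vertical templates decay exponentially from the most anterior
#' row toward posterior channels; the horizontal (saccade) template is
#' left/right antisymmetric.
#'
#' @param rate Sampling rate, Hz.
#' @param layout `electrode_layout` supplying 2D positions.
#' @param kind `"blink"`, `"vertical"` or `"horizontal"`.
#' @param amplitude Peak amplitude (microvolts) at the most frontal row.
#' @param decay Anterior-posterior spatial decay constant (head radii).
#' @return List with `waveform` (unit peak) and `profile` (named vector of
#'   per-channel amplitudes).
#' @export
default_eog_template <- function(rate, layout = standard_layout(),
                                 kind = c("blink", "vertical", "horizontal"),
                                 amplitude = 80, decay = 0.3) {
  kind <- match.arg(kind)
  y <- layout$positions[, "y"]
  x <- layout$positions[, "x"]
  front <- max(y)
  prof <- amplitude * exp(-(front - y) / decay)
  dur <- switch(kind, blink = 0.35, vertical = 0.8, horizontal = 0.9)
  n <- max(4L, as.integer(round(dur * rate)))
  tt <- seq(0, 1, length.out = n)
  wave <- switch(kind,
    blink = sin(pi * tt)^2,
    vertical = sin(pi * tt)^2 * (1 - 0.3 * tt),
    horizontal = {                       # smoothed step (gaze shift and back)
      ramp <- pmin(1, pmin(tt, 1 - tt) / 0.15)
      ramp
    })
  if (kind == "horizontal") {
    prof <- prof * tanh(x / 0.3)         # left/right antisymmetric
  }
  names(prof) <- layout$names
  list(waveform = wave, profile = prof, kind = kind)
}

#' Inject transient ocular artifacts
#'
#' Adds template artifacts at Poisson-distributed times and returns the
#' injection log, so downstream correction can be tested against the held-
#' out clean signal.
#'
#' @param rec A `recording`.
#' @param rate_per_min Expected artifact rate, events per minute (>= 0).
#' @param template A template from [default_eog_template()].
#' @param seed Optional RNG seed for reproducible injection.
#' @return List with the modified `recording` and `log` (data frame:
#'   onset sample and per-event amplitude scale).
#' @export
inject_eog <- function(rec, rate_per_min, template, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (rate_per_min < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- n_samples(rec)
  wave <- template$waveform
  if (length(wave) >= n) stop("template longer than recording", call. = FALSE)
  prof <- template$profile[rec$labels]
  prof[is.na(prof)] <- 0
  n_ev <- stats::rpois(1, rate_per_min * n / rec$rate / 60)
  log <- data.frame(sample = integer(), scale = numeric())
  if (n_ev > 0) {
    onsets <- sort(sample.int(n - length(wave), n_ev))
    scales <- exp(stats::rnorm(n_ev, 0, 0.2))
    for (i in seq_len(n_ev)) {
      cols <- onsets[i]:(onsets[i] + length(wave) - 1L)
      rec$signal[, cols] <- rec$signal[, cols] +
        outer(prof * scales[i], wave)
    }
    log <- data.frame(sample = onsets - 1L, scale = scales)
  }
  list(recording = rec, log = log)
}

# Calibration recording: three eye-movement sequences (blinks, vertical,
# horizontal), each generating maximal ocular activity, over a low-level
# EEG background.  Used to fit the ocular-interference model.
simulate_calibration <- function(cfg, layout = standard_layout(cfg$montage),
                                 seconds_each = 10) {
  rate <- cfg$rate
  labs <- layout$names
  n_seg <- as.integer(seconds_each * rate)
  n <- 3L * n_seg
  n_full <- stats::nextn(n, c(2, 3, 5))
  k <- seq_len(n_full) - 1L
  f_grid <- pmin(k, n_full - k) * rate / n_full
  psd_n <- noise_psd(f_grid, cfg$noise)
  sig <- matrix(0, length(labs), n)
  for (ch in seq(1L, length(labs), by = 2L)) {
    z <- shaped_noise_pair(n_full, rate, psd_n)
    sig[ch, ] <- Re(z)[seq_len(n)]
    if (ch + 1L <= length(labs)) sig[ch + 1L, ] <- Im(z)[seq_len(n)]
  }
  rec <- recording(sig, rate, labs)
  amp <- cfg$eog$amplitude
  kinds <- c("blink", "vertical", "horizontal")
  gaps <- c(1.2, 2.0, 1.8)
  for (s in 1:3) {
    tpl <- default_eog_template(rate, layout, kinds[s], amp * 1.2,
                                cfg$eog$decay)
    onsets <- seq((s - 1) * seconds_each + 0.5, s * seconds_each - 1.5,
                  by = gaps[s])
    for (t0 in onsets) {
      cols <- sec_to_sample(t0, rate) + seq_along(tpl$waveform)
      scl <- exp(stats::rnorm(1, 0, 0.1))
      rec$signal[, cols] <- rec$signal[, cols] +
        outer(tpl$profile[labs] * scl, tpl$waveform)
    }
  }
  rec
}

#' Simulate a grip-force trace
#'
#' Per-finger force time series covering the orientation and action phases
#' of one motor trial.  With `success_target = TRUE` the mean force stays
#' within the target interval for at least 80% of action-phase samples (by
#' construction it never leaves it); with `FALSE` it settles above the
#' interval and violates the criterion.
#'
#' @param trial_type `"MT_LOW"` or `"MT_HIGH"`.
#' @param cfg A `simulation_config`.
#' @param success_target Should the trace satisfy the success criterion?
#' @return A `force_trace`: matrix fingers x samples (newtons) with
#'   attributes `rate`, `trial_type`, `action_start` (0-based sample).
#' @export
simulate_force <- function(trial_type, cfg, success_target = TRUE) {
  if (!trial_type %in% c("MT_LOW", "MT_HIGH")) {
    stop("force traces exist only for motor trials (MT_LOW, MT_HIGH)",
         call. = FALSE)
  }
  rate <- cfg$rate
  f0 <- cfg$force$target[[trial_type]]
  tol <- cfg$force$tolerance[[trial_type]]
  n_f <- cfg$force$n_fingers
  n_orient <- as.integer(round(cfg$timing$orientation * rate))
  n_action <- as.integer(round(cfg$timing$action * rate))
  n <- n_orient + n_action
  tr <- matrix(0, n_f, n)
  ramp_n <- min(n_orient, as.integer(rate))
  for (fi in seq_len(n_f)) {
    # slowly wandering bounded deviation around the target
    z <- stats::rnorm(ceiling(n / rate * 4))        # ~4 Hz innovations
    z <- stats::approx(seq_along(z), z, n = n)$y
    dev <- tol * 0.7 * tanh(z)
    offset <- if (success_target) 0 else 2.2 * tol
    trace <- f0 * (1 + dev + offset)
    trace[seq_len(ramp_n)] <- trace[seq_len(ramp_n)] *
      seq(0, 1, length.out = ramp_n)
    tr[fi, ] <- pmax(trace, 0)
  }
  structure(tr, rate = rate, trial_type = trial_type,
            action_start = n_orient, class = c("force_trace", "matrix"))
}
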