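# Single-trial FFT amplitude spectra, band activations and ERD/ERS maps.
#
# The per-trial, per-electrode feature of the whole analysis is the FFT
# magnitude spectrum of the 2-s window (0.5 Hz bins at 128 Hz), averaged
# over the bins of a frequency band.  The condition activation averages
# that quantity additionally over trials; the relative power change
# against the rest baseline defines ERD (negative) and ERS (positive).

#' Amplitude spectrum of one epoch
#'
#' Magnitude spectrum of the 2-s analysis window, per channel.  Amplitudes
#' are scaled such that a unit sinusoid at a bin frequency yields amplitude
#' 1 in its bin.  Rectangular window by default; a Hann taper is available
#' but the analysis convention is no taper.
#'
#' @param epoch Numeric matrix channels x samples, or a vector.
#' @param rate Sampling rate, Hz.
#' @param expected_seconds Required window length (seconds); set `NULL` to
#'   skip the check.
#' @param window `"rectangular"` or `"hann"`.
#' @return An `amplitude_spectrum`: list with `freq` (Hz) and `amp`
#'   (channels x bins matrix, nonnegative).
#' @export
epoch_spectrum <- function(epoch, rate, expected_seconds = 2,
                           window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (!is.null(expected_seconds) &&
      n != as.integer(round(expected_seconds * rate))) {
    stop(sprintf("epoch must be %g s at %g Hz (%d samples), got %d",
                 expected_seconds, rate, as.integer(expected_seconds * rate),
                 n), call. = FALSE)
  }
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq.int(0, n - 1) / n)
  } else rep(1, n)
  wn <- w / sum(w) * n                      # unit-gain normalization
  X <- stats::mvfft(t(epoch * rep(wn, each = nrow(epoch))))
  half <- n %/% 2 + 1L
  amp <- t(Mod(X[seq_len(half), , drop = FALSE])) * (2 / n)
  amp[, 1] <- amp[, 1] / 2
  if (n %% 2 == 0) amp[, half] <- amp[, half] / 2
  structure(list(freq = (seq_len(half) - 1L) * rate / n, amp = amp),
            class = "amplitude_spectrum")
}

#' Frequency-band bin selector
#'
#' Bins whose center frequency f satisfies `low <= f <= high` (inclusive
#' edges, matching the 8-13 Hz / 14-30 Hz band phrasing on the 0.5 Hz
#' grid: 13.0 Hz belongs to alpha, 13.5 Hz does not).
#'
#' @param freq Bin center frequencies, Hz.
#' @param band Length-2 numeric `(low, high)`, Hz.
#' @return Logical vector over bins.
#' @export
band_bins <- function(freq, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("empty frequency band", call. = FALSE)
  sel
}

#' Standard analysis bands
#' @return Named list with `alpha` (8-13 Hz) and `beta` (14-30 Hz) edges.
#' @export
analysis_bands <- function() list(alpha = c(8, 13), beta = c(14, 30))

#' Per-trial band amplitudes for every electrode
#'
#' The inner mean of the condition-activation double average: per trial and
#' electrode, the amplitude-spectrum values averaged over the band bins.
#' Trials that are masked at an electrode yield `NA` there and are omitted
#' from that electrode's averages only.
#'
#' @param epochs An `epoch_collection`.
#' @param band Band edges (Hz).
#' @param window Spectral window, see [epoch_spectrum()].
#' @return Matrix trials x channels of band amplitudes (`NA` where the
#'   electrode is invalid in that trial).
#' @export
band_amplitudes <- function(epochs, band, window = "rectangular") {
  n_ep <- length(epochs$condition)
  out <- matrix(NA_real_, n_ep, length(epochs$labels),
                dimnames = list(NULL, epochs$labels))
  for (i in seq_len(n_ep)) {
    sp <- epoch_spectrum(epochs$data[, , i], epochs$rate,
                         expected_seconds = dim(epochs$data)[2] / epochs$rate,
                         window = window)
    sel <- band_bins(sp$freq, band)
    out[i, ] <- rowMeans(sp$amp[, sel, drop = FALSE])
  }
  out[t(!epochs$valid)] <- NA_real_
  out
}

#' Condition activation (double average over band bins and trials)
#'
#' @param spectra Either a trials x channels matrix from
#'   [band_amplitudes()] or a list of `amplitude_spectrum` objects (one per
#'   trial).
#' @param band Band edges (Hz); required when `spectra` is a list.
#' @return Named numeric vector: per-electrode activation.
#' @export
condition_activation <- function(spectra, band = NULL) {
  if (is.list(spectra) && !is.data.frame(spectra)) {
    stopifnot(length(spectra) >= 1, !is.null(band))
    per_trial <- vapply(spectra, function(sp) {
      sel <- band_bins(sp$freq, band)
      rowMeans(sp$amp[, sel, drop = FALSE])
    }, numeric(nrow(spectra[[1]]$amp)))
    if (is.null(dim(per_trial))) per_trial <- matrix(per_trial, nrow = 1)
    rowMeans(per_trial)
  } else {
    stopifnot(is.matrix(spectra), nrow(spectra) >= 1)
    colMeans(spectra, na.rm = TRUE)
  }
}

#' Relative power change against the rest baseline
#'
#' `(exp - rest) / rest`: negative values are event-related
#' desynchronization (ERD), positive values event-related synchronization
#' (ERS).  Values are signed fractions; multiply by 100 for percent.
#'
#' @param exp_E Activation(s) under the experimental condition.
#' @param rest_E Matching rest activation(s) (> 0).
#' @return Signed fraction(s), same shape as the inputs.
#' @export
relative_power_change <- function(exp_E, rest_E) {
  if (any(rest_E <= 0, na.rm = TRUE)) {
    stop("rest activation must be positive", call. = FALSE)
  }
  (exp_E - rest_E) / rest_E
}

#' ERD/ERS scalp map for one condition and band
#'
#' Per-electrode relative power change of a condition against rest epochs
#' of matching block origin, with a per-electrode p-value from a Welch
#' t-test on the per-trial log band amplitudes.  Electrodes excluded from
#' the analysis are flagged `removed` and carry `NA` values.
#'
#' @param epochs An `epoch_collection` containing the condition and
#'   matching-origin rest epochs.
#' @param condition Condition name (e.g. `"MT_HIGH"`).
#' @param band Band edges (Hz) or a band name from [analysis_bands()].
#' @param min_trials Minimal per-electrode trial count on each side.
#' @return An `erd_map`: data frame with columns `electrode`, `band`,
#'   `condition`, `origin`, `power_change` (signed fraction), `percent`,
#'   `n_exp`, `n_rest`, `p_value`, `removed`.
#' @export
erd_scalp_map <- function(epochs, condition, band = "alpha", min_trials = 2) {
  band_name <- if (is.character(band)) band else "custom"
  if (is.character(band)) band <- analysis_bands()[[band]]
  stopifnot(length(band) == 2)
  origin <- substr(condition, 1, 2)
  is_exp <- epochs$condition == condition
  is_rest <- epochs$condition == "REST" & epochs$origin == origin
  if (!any(is_exp)) stop("no epochs of condition ", condition, call. = FALSE)
  if (!any(is_rest)) {
    stop("no rest epochs of matching origin (", origin, ")", call. = FALSE)
  }
  amps <- band_amplitudes(epochs, band)
  labs <- epochs$labels
  res <- data.frame(electrode = labs, band = band_name,
                    condition = condition, origin = origin,
                    power_change = NA_real_, percent = NA_real_,
                    n_exp = 0L, n_rest = 0L, p_value = NA_real_,
                    removed = FALSE, stringsAsFactors = FALSE)
  for (ch in seq_along(labs)) {
    a_exp <- amps[is_exp, ch]; a_exp <- a_exp[!is.na(a_exp)]
    a_rest <- amps[is_rest, ch]; a_rest <- a_rest[!is.na(a_rest)]
    res$n_exp[ch] <- length(a_exp); res$n_rest[ch] <- length(a_rest)
    if (length(a_exp) < min_trials || length(a_rest) < min_trials) {
      res$removed[ch] <- TRUE
      next
    }
    pc <- relative_power_change(mean(a_exp), mean(a_rest))
    res$power_change[ch] <- pc
    res$percent[ch] <- 100 * pc
    res$p_value[ch] <- stats::t.test(log(a_exp), log(a_rest))$p.value
  }
  class(res) <- c("erd_map", "data.frame")
  res
}

#' Write an ERD map as CSV
#' @param map An `erd_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_erd_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
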