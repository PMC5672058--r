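# The continuous-recording container used by every pipeline stage.

#' Construct a Recording
#'
#' A `recording` bundles a continuous multichannel EEG signal with its
#' sampling rate, channel labels, event table and a per-channel per-sample
#' validity mask.  All stages of the pipeline consume and return this
#' container.  Sample indices are 0-based and windows are half-open
#' `[start, end)`; times in seconds are converted at `rate`.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz (> 0).
#' @param labels Character vector of channel names (one per row of `signal`).
#' @param events Data frame with at least columns `sample` (0-based integer),
#'   `code` (character).  Optional columns: `condition`, `block`, `trial`,
#'   `success`.  Missing optional columns are filled with `NA`.
#' @param validity Logical matrix, same dimensions as `signal`; `TRUE` marks
#'   a valid sample.  Defaults to all-valid.
#' @param excluded Character vector of channel labels excluded from analysis.
#' @return An object of class `recording`.
#' @export
recording <- function(signal, rate, labels, events = NULL, validity = NULL,
                      excluded = character()) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  stopifnot_scalar_number(rate, "rate", min = 1e-9)
  stopifnot(length(labels) == nrow(signal))
  if (is.null(validity)) {
    validity <- matrix(TRUE, nrow(signal), ncol(signal))
  }
  stopifnot(is.logical(validity), all(dim(validity) == dim(signal)))
  events <- normalize_events(events, n_samples = ncol(signal))
  rownames(signal) <- labels
  rownames(validity) <- labels
  structure(
    list(signal = signal, rate = rate, labels = as.character(labels),
         events = events, validity = validity,
         excluded = as.character(excluded)),
    class = "recording")
}

normalize_events <- function(events, n_samples) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    return(data.frame(sample = integer(), code = character(),
                      condition = character(), origin = character(),
                      block = integer(), trial = integer(),
                      success = logical(), stringsAsFactors = FALSE))
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "code") %in% names(events)))
  for (col in c("condition", "origin")) {
    if (is.null(events[[col]])) events[[col]] <- NA_character_
  }
  for (col in c("block", "trial")) if (is.null(events[[col]])) events[[col]] <- NA_integer_
  if (is.null(events$success)) events$success <- NA
  events$sample <- as.integer(events$sample)
  if (any(events$sample < 0L) || any(events$sample >= n_samples)) {
    stop("event sample indices must lie within the recording", call. = FALSE)
  }
  events[order(events$sample), , drop = FALSE]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate))
  cat(sprintf("  events: %d   excluded channels: %s\n", nrow(x$events),
              if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none"))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec A `recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$signal)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$signal)

# Indices of channels that are not excluded.
active_channels <- function(rec) which(!(rec$labels %in% rec$excluded))

# Fraction of invalid samples per channel.
invalid_fraction <- function(rec) 1 - rowMeans(rec$validity)
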