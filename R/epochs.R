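# Trial bookkeeping: motor-trial success evaluation and extraction of the
# 2-s analysis window from each successful trial's action phase.

new_epoch_collection <- function(data, rate, labels, condition, block,
                                 origin, trial, valid) {
  structure(list(data = data, rate = rate, labels = labels,
                 condition = condition, block = block, origin = origin,
                 trial = trial, valid = valid),
            class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  cat(sprintf("<epoch_collection> %d epochs x %d channels x %d samples @ %g Hz\n",
              length(x$condition), dim(x$data)[1], dim(x$data)[2], x$rate))
  print(table(condition = x$condition, origin = x$origin))
  invisible(x)
}

#' Number of epochs per condition
#' @param epochs An `epoch_collection`.
#' @return Named integer vector.
#' @export
epoch_counts <- function(epochs) {
  c(table(epochs$condition))
}

#' Evaluate the success of a motor trial from its force trace
#'
#' A motor trial is successful when the grip force stays within the target
#' interval for at least 80% of the 3-s action phase (total time, evaluated
#' on discrete samples with a `>=` comparison).  The target interval is
#' 2.5 N +/- 20% per finger for low-force trials and 6.5 N +/- 10% for
#' high-force trials.  By default the across-finger mean force is compared
#' against the interval at each sample; `per_finger_strict = TRUE` instead
#' requires every finger to be individually within its interval.
#'
#' @param force A `force_trace` from [simulate_force()] (fingers x samples,
#'   with attributes `rate` and `action_start`), or a plain matrix plus
#'   `rate`/`action_start` arguments.
#' @param trial_type `"MT_LOW"` or `"MT_HIGH"`.
#' @param cfg A `simulation_config` supplying targets and action duration.
#' @param per_finger_strict Require each finger within its own interval.
#' @param rate,action_start Overrides when `force` is a plain matrix.
#' @return `TRUE` iff the success criterion is met.
#' @export
evaluate_trial_success <- function(force, trial_type, cfg = simulation_config(),
                                   per_finger_strict = FALSE,
                                   rate = attr(force, "rate"),
                                   action_start = attr(force, "action_start")) {
  if (!trial_type %in% c("MT_LOW", "MT_HIGH")) {
    stop("success is defined only for motor trials", call. = FALSE)
  }
  stopifnot(is.matrix(force), !is.null(rate), !is.null(action_start))
  n_action <- as.integer(round(cfg$timing$action * rate))
  if (ncol(force) < action_start + n_action) {
    stop("force trace shorter than the action phase", call. = FALSE)
  }
  f0 <- cfg$force$target[[trial_type]]
  tol <- cfg$force$tolerance[[trial_type]]
  lo <- f0 * (1 - tol); hi <- f0 * (1 + tol)
  cols <- (action_start + 1L):(action_start + n_action)
  seg <- force[, cols, drop = FALSE]
  in_range <- if (per_finger_strict) {
    apply(seg >= lo & seg <= hi, 2, all)
  } else {
    m <- colMeans(seg)
    m >= lo & m <= hi
  }
  mean(in_range) >= 0.8
}

#' Extract 2-s analysis epochs from a preprocessed recording
#'
#' One epoch per successful trial, windowed `[onset + 0.5 s, onset + 2.5 s)`
#' relative to the action-phase onset marker, during which the grip force
#' (or stimulation) is constant.  Unsuccessful trials are omitted.  Rest
#' epochs carry the block type they came from as `origin` ("MT" or "SS"),
#' because rest trials from motor and stimulation blocks serve as separate
#' baselines and are never pooled silently.  Channels masked anywhere
#' inside the window are flagged invalid for that epoch; excluded channels
#' are invalid in every epoch.
#'
#' @param rec A preprocessed `recording` (128 Hz) whose events contain
#'   `action_start` markers with condition/block/success metadata.
#' @param events Optional replacement event table (defaults to
#'   `rec$events`).
#' @param window Epoch window relative to the action onset, seconds
#'   (half-open).
#' @return An `epoch_collection`.
#' @export
extract_epochs <- function(rec, events = rec$events, window = c(0.5, 2.5)) {
  stopifnot(inherits(rec, "recording"))
  ev <- events[events$code == "action_start", , drop = FALSE]
  if (!nrow(ev)) stop("no action_start markers present", call. = FALSE)
  keep <- is.na(ev$success) | ev$success
  ev <- ev[keep, , drop = FALSE]
  w0 <- sec_to_sample(window[1], rec$rate)
  w1 <- sec_to_sample(window[2], rec$rate)
  len <- w1 - w0
  n_ep <- nrow(ev)
  first <- ev$sample + w0
  if (any(first < 0) || any(first + len > n_samples(rec))) {
    stop("epoch window exceeds recording bounds", call. = FALSE)
  }
  n_ch <- n_channels(rec)
  data <- array(NA_real_, c(n_ch, len, n_ep))
  valid <- matrix(TRUE, n_ch, n_ep)
  excluded_idx <- which(rec$labels %in% rec$excluded)
  origin <- substr(ev$condition, 1, 2)
  if (!is.null(ev$origin) && !all(is.na(ev$origin))) {
    origin <- ev$origin
  } else if (any(ev$condition == "REST")) {
    # infer each block's type from its non-rest trials
    nonrest <- events[events$code == "action_start" &
                        events$condition != "REST", , drop = FALSE]
    bt_map <- tapply(substr(nonrest$condition, 1, 2), nonrest$block,
                     function(x) unique(x)[1])
    is_rest <- ev$condition == "REST"
    origin[is_rest] <- unname(bt_map[as.character(ev$block[is_rest])])
    origin[is.na(origin)] <- "MT"
  }
  for (i in seq_len(n_ep)) {
    cols <- (first[i] + 1L):(first[i] + len)
    data[, , i] <- rec$signal[, cols, drop = FALSE]
    valid[, i] <- rowSums(!rec$validity[, cols, drop = FALSE]) == 0L
  }
  if (length(excluded_idx)) valid[excluded_idx, ] <- FALSE
  new_epoch_collection(data = data, rate = rec$rate, labels = rec$labels,
                       condition = ev$condition, block = ev$block,
                       origin = origin, trial = ev$trial, valid = valid)
}

#' Subset an epoch collection
#'
#' @param epochs An `epoch_collection`.
#' @param idx Logical or integer index over epochs.
#' @return The subsetted `epoch_collection`.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epoch_collection(
    data = epochs$data[, , idx, drop = FALSE], rate = epochs$rate,
    labels = epochs$labels, condition = epochs$condition[idx],
    block = epochs$block[idx], origin = epochs$origin[idx],
    trial = epochs$trial[idx], valid = epochs$valid[, idx, drop = FALSE])
}

#' Trial table of an epoch collection
#'
#' @param epochs An `epoch_collection`.
#' @return Data frame (trial, condition, block, origin, n_valid_channels).
#' @export
trial_table <- function(epochs) {
  data.frame(trial = epochs$trial, condition = epochs$condition,
             block = epochs$block, origin = epochs$origin,
             n_valid_channels = colSums(epochs$valid))
}
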