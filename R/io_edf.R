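# Minimal EDF(+) reader and writer.
#
# Signals are stored as 16-bit little-endian integers with per-signal
# physical/digital scaling, in records of 1 s.  Events are carried in an
# "EDF Annotations" signal using time-stamped annotation lists (TAL), so a
# written file round-trips both the signal (within 16-bit quantization) and
# the full event table.  The final partial second is zero-padded on write
# and the pad is kept on read (EDF stores whole records only).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' @param rec A `recording`.
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  n_ch <- n_channels(rec)
  n_rec <- as.integer(ceiling(n_samples(rec) / rate))

  # per-channel physical range -> digital scaling
  phys_min <- apply(rec$signal, 1, min)
  phys_max <- apply(rec$signal, 1, max)
  margin <- pmax((phys_max - phys_min) * 1e-3, 1e-3)
  phys_min <- phys_min - margin
  phys_max <- phys_max + margin
  dmin <- -32768; dmax <- 32767

  ann <- edf_annotation_records(rec$events, rate, n_rec)
  ann_len <- max(vapply(ann, length, 0L))         # bytes per record, even
  ann_len <- as.integer(ceiling(ann_len / 2) * 2)
  ns <- n_ch + 1L                                  # + annotations signal

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                                # local patient id
  wr("Startdate X X X X", 80)                      # local recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("EDF+C", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)

  lab <- c(edf_pad(rec$labels, 16), edf_pad("EDF Annotations", 16))
  wr(paste0(lab, collapse = ""), 16 * ns)
  wr(paste0(rep(edf_pad("", 80), ns), collapse = ""), 80 * ns)
  wr(paste0(c(rep(edf_pad("uV", 8), n_ch), edf_pad("", 8)), collapse = ""), 8 * ns)
  wr(paste0(edf_pad(sprintf("%.8g", c(phys_min, -1)), 8), collapse = ""), 8 * ns)
  wr(paste0(edf_pad(sprintf("%.8g", c(phys_max, 1)), 8), collapse = ""), 8 * ns)
  wr(paste0(edf_pad(c(rep(dmin, n_ch), dmin), 8), collapse = ""), 8 * ns)
  wr(paste0(edf_pad(c(rep(dmax, n_ch), dmax), 8), collapse = ""), 8 * ns)
  wr(paste0(rep(edf_pad("", 80), ns), collapse = ""), 80 * ns)
  wr(paste0(edf_pad(c(rep(rate, n_ch), ann_len %/% 2L), 8), collapse = ""), 8 * ns)
  wr(paste0(rep(edf_pad("", 32), ns), collapse = ""), 32 * ns)

  gain <- (dmax - dmin) / (phys_max - phys_min)
  sig <- rec$signal
  if (ncol(sig) < n_rec * rate) {
    sig <- cbind(sig, matrix(0, n_ch, n_rec * rate - ncol(sig)))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    dig <- round((sig[, cols, drop = FALSE] - phys_min) * gain) + dmin
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
    tal <- ann[[r]]
    pad <- raw(ann_len - length(tal))
    writeBin(c(tal, pad), con)
  }
  invisible(path)
}

# Build the raw TAL bytes for each 1-s record.
edf_annotation_records <- function(events, rate, n_rec) {
  ds <- as.raw(0x14); nul <- as.raw(0)
  lapply(seq_len(n_rec) - 1L, function(t0) {
    tal <- c(charToRaw(sprintf("+%d", t0)), ds, ds, nul)  # record time-keeping TAL
    if (nrow(events)) {
      onset <- events$sample / rate
      in_rec <- which(onset >= t0 & onset < t0 + 1)
      for (i in in_rec) {
        txt <- encode_marker_desc(events[i, , drop = FALSE])
        tal <- c(tal, charToRaw(sprintf("%+.7g", onset[i])), ds,
                 charToRaw(txt), ds, nul)
      }
    }
    tal
  })
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF/EDF+ files; an `EDF Annotations` signal, if present, is
#' parsed into the event table.  Channel labels are normalized to 10-10
#' montage spelling where possible.
#'
#' @param path Path to the `.edf` file.
#' @return A `recording` with an all-true validity mask.
#' @export
read_edf <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file: ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))   # samples per record
  field(32)

  is_ann <- labels == "EDF Annotations"
  n_ch <- sum(!is_ann)
  rate <- spr[!is_ann][1] / rec_dur
  if (n_ch && any(spr[!is_ann] != spr[!is_ann][1])) {
    stop("heterogeneous sampling rates are not supported", call. = FALSE)
  }

  chunks <- vector("list", n_rec)
  ann_raw <- raw()
  for (r in seq_len(n_rec)) {
    rec_list <- vector("list", ns)
    for (s in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[s], size = 2L, endian = "little")
      rec_list[[s]] <- vals
    }
    mat <- do.call(rbind, lapply(which(!is_ann), function(s) {
      gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      (rec_list[[s]] - dmin[s]) * gain + pmin[s]
    }))
    chunks[[r]] <- mat
    for (s in which(is_ann)) {
      ann_raw <- c(ann_raw, writeBin(as.integer(rec_list[[s]]), raw(),
                                     size = 2L, endian = "little"))
    }
  }
  signal <- do.call(cbind, chunks)
  labels <- normalize_labels(labels[!is_ann])
  events <- if (length(ann_raw)) parse_edf_annotations(ann_raw, rate) else NULL
  recording(signal, rate, labels, events = events)
}

parse_edf_annotations <- function(bytes, rate) {
  # split the raw stream on NUL terminators, one chunk per TAL
  nul_at <- which(bytes == as.raw(0))
  if (!length(nul_at)) return(NULL)
  starts <- c(1L, utils::head(nul_at, -1) + 1L)
  tals <- mapply(function(s, e) if (e >= s) rawToChar(bytes[s:e]) else "",
                 starts, nul_at - 1L)
  out <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[1])) next
    desc <- parts[-1]
    desc <- desc[nzchar(desc)]
    if (!length(desc)) next                      # time-keeping TAL
    onset <- as.numeric(sub("\x15.*$", "", parts[1]))
    for (d in desc) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(sample = as.integer(round(onset * rate))),
        decode_marker_desc(d))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
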