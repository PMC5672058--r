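# BrainVision (.vhdr/.eeg/.vmrk) reader and writer.
#
# Dialect written here: binary IEEE float32, little-endian, multiplexed
# samples, with markers stored in the .vmrk text file.  Marker positions in
# the files are 1-based (format convention); the in-memory `recording` uses
# 0-based samples, so +/- 1 is applied at the boundary.

#' Write a recording as a BrainVision triplet
#'
#' @param rec A `recording`.
#' @param path Path of the header file; must end in `.vhdr`.  The data and
#'   marker files are written next to it with extensions `.eeg` / `.vmrk`.
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "recording"), grepl("\\.vhdr$", path))
  base <- sub("\\.vhdr$", "", basename(path))
  dir <- dirname(path)
  eeg_file <- paste0(base, ".eeg")
  vmrk_file <- paste0(base, ".vmrk")

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg_file),
    paste0("MarkerFile=", vmrk_file),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_channels(rec)),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_channels(rec)), rec$labels))
  writeLines(hdr, file.path(dir, paste0(base, ".vhdr")))

  con <- file(file.path(dir, eeg_file), "wb")
  on.exit(close(con), add = TRUE)
  # multiplexed: sample-major interleaving = column-major of channels x samples
  writeBin(as.vector(rec$signal), con, size = 4L, endian = "little")

  mrk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg_file),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events)) {
    desc <- encode_marker_desc(rec$events)
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L, desc,
                          rec$events$sample + 1L))
  }
  writeLines(mrk, file.path(dir, vmrk_file))
  invisible(path)
}

# Marker description encodes the event metadata the format has no fields for.
encode_marker_desc <- function(events) {
  desc <- events$code
  add <- function(desc, key, val) {
    has <- !is.na(val)
    desc[has] <- paste0(desc[has], ";", key, "=", val[has])
    desc
  }
  desc <- add(desc, "cond", events$condition)
  desc <- add(desc, "orig", events$origin)
  desc <- add(desc, "block", events$block)
  desc <- add(desc, "trial", events$trial)
  desc <- add(desc, "success", ifelse(is.na(events$success), NA,
                                      as.integer(events$success)))
  desc
}

decode_marker_desc <- function(desc) {
  parts <- strsplit(desc, ";", fixed = TRUE)
  get <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  data.frame(
    code = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, get, "", "cond"),
    origin = vapply(parts, get, "", "orig"),
    block = as.integer(vapply(parts, get, "", "block")),
    trial = as.integer(vapply(parts, get, "", "trial")),
    success = as.logical(as.integer(vapply(parts, get, "", "success"))),
    stringsAsFactors = FALSE)
}

read_ini_sections <- function(lines) {
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", trimws(ln))
      out[[section]] <- character()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      out[[section]] <- c(out[[section]], ln)
    }
  }
  out
}

ini_value <- function(entries, key) {
  hit <- grep(paste0("^", key, "="), entries, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision recording
#'
#' Supports the dialect written by [write_brainvision()] plus 16/32-bit
#' integer binary formats.  Channel labels are normalized to 10-10 montage
#' spelling where possible; unmappable labels are kept and reported.
#'
#' @param path Path to the `.vhdr` header file.
#' @return A `recording` with an all-true validity mask.
#' @export
read_brainvision <- function(path) {
  stopifnot(file.exists(path))
  hdr <- read_ini_sections(readLines(path, warn = FALSE))
  common <- hdr[["Common Infos"]]
  if (is.null(common)) stop("not a BrainVision header: ", path, call. = FALSE)
  if (!identical(toupper(ini_value(common, "DataFormat")), "BINARY") ||
      !identical(toupper(ini_value(common, "DataOrientation")), "MULTIPLEXED")) {
    stop("only binary multiplexed BrainVision data is supported", call. = FALSE)
  }
  n_ch <- as.integer(ini_value(common, "NumberOfChannels"))
  rate <- 1e6 / as.numeric(ini_value(common, "SamplingInterval"))
  fmt <- toupper(ini_value(hdr[["Binary Infos"]], "BinaryFormat") %||% "IEEE_FLOAT_32")

  ch_entries <- hdr[["Channel Infos"]]
  ch_fields <- strsplit(sub("^Ch[0-9]+=", "", ch_entries), ",")
  labels <- vapply(ch_fields, `[`, "", 1L)
  res <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3])); if (is.na(r)) 1 else r
  }, 0)
  labels <- normalize_labels(labels)

  eeg_path <- file.path(dirname(path), ini_value(common, "DataFile"))
  size <- switch(fmt, IEEE_FLOAT_32 = 4L, INT_32 = 4L, INT_16 = 2L,
                 stop("unsupported BinaryFormat: ", fmt, call. = FALSE))
  what <- if (fmt == "IEEE_FLOAT_32") numeric() else integer()
  n_val <- file.size(eeg_path) %/% size
  raw <- readBin(eeg_path, what, n = n_val, size = size, endian = "little")
  if (fmt != "IEEE_FLOAT_32") raw <- raw * rep(res, length.out = length(raw))
  signal <- matrix(raw, nrow = n_ch)

  events <- NULL
  vmrk <- ini_value(common, "MarkerFile")
  vmrk_path <- file.path(dirname(path), vmrk)
  if (!is.na(vmrk) && file.exists(vmrk_path)) {
    mhdr <- read_ini_sections(readLines(vmrk_path, warn = FALSE))
    mk <- mhdr[["Marker Infos"]]
    if (length(mk)) {
      fields <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
      type <- vapply(fields, `[`, "", 1L)
      keep <- type != "New Segment"
      if (any(keep)) {
        desc <- vapply(fields[keep], `[`, "", 2L)
        pos <- as.integer(vapply(fields[keep], `[`, "", 3L)) - 1L
        events <- cbind(data.frame(sample = pos), decode_marker_desc(desc))
      }
    }
  }
  recording(signal, rate, labels, events = events)
}
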