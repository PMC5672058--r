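# Format dispatch and the portable epoch container.

#' Read a continuous recording
#'
#' Thin dispatcher over the format-specific readers.
#'
#' @param path File path (`.edf`, or a BrainVision `.vhdr`).
#' @param dialect `"EDF"` or `"BrainVision"`; inferred from the file
#'   extension when omitted.
#' @return A `recording`.
#' @export
read_recording <- function(path, dialect = c("auto", "EDF", "BrainVision")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "EDF"
               else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "BrainVision"
               else stop("cannot infer dialect from extension: ", path, call. = FALSE)
  }
  switch(dialect,
         EDF = read_edf(path),
         BrainVision = read_brainvision(path))
}

#' Write a continuous recording
#'
#' @param rec A `recording`.
#' @param path Output path; the extension selects the dialect unless given.
#' @param dialect `"EDF"` or `"BrainVision"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("auto", "EDF", "BrainVision")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "EDF"
               else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "BrainVision"
               else stop("cannot infer dialect from extension: ", path, call. = FALSE)
  }
  switch(dialect,
         EDF = write_edf(rec, path),
         BrainVision = write_brainvision(rec, path))
}

#' Write an epoch collection to a portable directory
#'
#' The container is deliberately language-agnostic and diffable: a
#' `meta.json` with rate, labels and the trial table, plus one CSV matrix
#' (channels x samples) per epoch and a validity table.
#'
#' @param epochs An `epoch_collection` (see [extract_epochs()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(epochs$condition)
  meta <- list(
    rate = epochs$rate,
    labels = epochs$labels,
    n_epochs = n,
    trials = data.frame(
      epoch = seq_len(n), condition = epochs$condition,
      block = epochs$block, origin = epochs$origin,
      trial = epochs$trial,
      file = sprintf("epoch_%03d.csv", seq_len(n))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (i in seq_len(n)) {
    m <- as.data.frame(epochs$data[, , i])
    names(m) <- sprintf("s%03d", seq_len(ncol(m)) - 1L)
    utils::write.csv(cbind(channel = epochs$labels, m),
                     file.path(dir, sprintf("epoch_%03d.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(
    cbind(data.frame(channel = epochs$labels),
          as.data.frame(epochs$valid * 1L)),
    file.path(dir, "validity.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an epoch collection written by [write_epochs()]
#'
#' @param dir Container directory.
#' @return An `epoch_collection`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- meta$n_epochs
  labels <- meta$labels
  data <- NULL
  for (i in seq_len(n)) {
    m <- utils::read.csv(file.path(dir, meta$trials$file[i]), check.names = FALSE)
    mat <- as.matrix(m[, -1, drop = FALSE])
    if (is.null(data)) data <- array(NA_real_, c(nrow(mat), ncol(mat), n))
    data[, , i] <- mat
  }
  v <- utils::read.csv(file.path(dir, "validity.csv"))
  valid <- as.matrix(v[, -1, drop = FALSE]) == 1L
  new_epoch_collection(
    data = data, rate = meta$rate, labels = labels,
    condition = meta$trials$condition, block = meta$trials$block,
    origin = meta$trials$origin, trial = meta$trials$trial, valid = valid)
}
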