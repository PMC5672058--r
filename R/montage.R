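# Electrode layout handling for the 64-channel 10-10 montage.

#' The 20 sensorimotor feature electrodes
#'
#' Fixed, ordered electrode set used to build classification feature vectors.
#' Covers bilateral fronto-central, central, centro-parietal and parietal
#' sites.  The order is part of the feature-vector contract and must not be
#' permuted between training and testing.
#'
#' Note: published electrode lists occasionally print "CF3"; no CF row exists
#' in the 10-10 system and the label is resolved to FC3 here.  Override by
#' passing your own electrode vector to [build_features()].
#'
#' @return Character vector of 20 electrode labels.
#' @export
feature_electrodes <- function() {
  c("FC3", "FC1", "FCz", "FC2", "FC4",
    "C4",  "C2",  "Cz",  "C1",  "C3",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "P4",  "P2",  "Pz",  "P1",  "P3")
}

#' Standard electrode layout
#'
#' Returns the packaged 64-electrode 10-10 scalp layout used throughout the
#' package: electrode labels, 2D projected scalp coordinates (head radius 1,
#' nose up, left hemisphere at negative x) and a hemisphere tag per label.
#' Positions are a schematic azimuthal projection intended for topographic
#' display and for spatial rules (e.g. anterior-posterior ocular-artifact
#' decay), not for source modelling.
#'
#' @param name Montage identifier.  Only `"10-10-64"` is supported.
#' @return An object of class `electrode_layout`: a list with `names`
#'   (character), `positions` (64 x 2 matrix, columns `x`, `y`) and
#'   `hemisphere` (factor with levels left/midline/right).
#' @export
standard_layout <- function(name = "10-10-64") {
  if (!identical(name, "10-10-64")) {
    stop("unsupported montage id: ", name, " (only \"10-10-64\" is available)",
         call. = FALSE)
  }
  path <- system.file("extdata", "montage-10-10-64.json", package = "mucross",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- cbind(x = raw$electrodes$x, y = raw$electrodes$y)
  rownames(pos) <- raw$electrodes$label
  layout <- list(
    names = raw$electrodes$label,
    positions = pos,
    hemisphere = factor(raw$electrodes$hemisphere,
                        levels = c("left", "midline", "right"))
  )
  class(layout) <- "electrode_layout"
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(!anyDuplicated(layout$names))
  missing <- setdiff(feature_electrodes(), layout$names)
  if (length(missing)) {
    stop("layout is missing feature electrodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # left/right mirror symmetry
  for (lab in layout$names[layout$hemisphere == "left"]) {
    twin <- mirror_label(lab)
    if (twin %in% layout$names) {
      pl <- layout$positions[lab, ]
      pr <- layout$positions[twin, ]
      stopifnot(isTRUE(all.equal(unname(pl["x"]), -unname(pr["x"]))),
                isTRUE(all.equal(unname(pl["y"]), unname(pr["y"]))))
    }
  }
  invisible(layout)
}

# Label of the mirror-symmetric electrode (odd <-> even numbering).
mirror_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
  if (length(m) != 3L) return(label)     # midline (z) labels map to themselves
  n <- as.integer(m[3])
  twin <- if (n %% 2L == 1L) n + 1L else n - 1L
  paste0(m[2], twin)
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> ", length(x$names), " electrodes (10-10)\n", sep = "")
  cat("  ", paste(utils::head(x$names, 10), collapse = " "), " ...\n", sep = "")
  invisible(x)
}

# Normalize free-form channel labels to montage spelling (case-insensitive).
# Labels that cannot be mapped are returned unchanged and reported via a
# warning, mirroring how unrecognized channels are retained on import.
normalize_labels <- function(labels, layout = standard_layout()) {
  idx <- match(toupper(labels), toupper(layout$names))
  out <- ifelse(is.na(idx), labels, layout$names[idx])
  if (anyNA(idx)) {
    warning("channel label(s) not in 10-10 montage, kept as-is: ",
            paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  out
}
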