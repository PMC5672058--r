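#!/usr/bin/env Rscript
# Group-level statistics over the cohort produced by
# 03_classification_study.R: a two-way ANOVA of classification accuracy
# (classifier x feature set) with Tukey-Kramer post hoc comparisons, and
# per-electrode condition comparisons of the alpha ERD values.

library(mucross)

out <- "results/04_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

acc_path <- "results/03_classification/accuracy.csv"
if (!file.exists(acc_path)) {
  stop("run analysis/03_classification_study.R first", call. = FALSE)
}
acc <- utils::read.csv(acc_path, comment.char = "#")
acc$classifier <- paste(acc$train, acc$test, sep = "/")

aov_res <- two_way_anova(acc$accuracy, acc$classifier, acc$features)
cat("two-way ANOVA of accuracy (classifier x feature set):\n")
print(as.data.frame(aov_res), digits = 4)
utils::write.csv(as.data.frame(aov_res),
                 file.path(out, "anova_accuracy.csv"), row.names = FALSE)

# post hoc: regular classifiers only, alpha features (4 groups)
reg <- acc[acc$type == "regular" & acc$features == "alpha", ]
tk <- tukey_kramer_groups(reg$accuracy, reg$train)
cat("\nTukey-Kramer, regular classifiers (alpha features):\n")
print(tk, digits = 3)
utils::write.csv(tk, file.path(out, "tukey_regular_alpha.csv"),
                 row.names = FALSE)

erd_path <- "results/03_classification/erd.csv"
if (file.exists(erd_path)) {
  erd <- utils::read.csv(erd_path, comment.char = "#")
  alpha <- erd[erd$band == "alpha" & !erd$removed &
                 erd$electrode %in% feature_electrodes(), ]
  res <- two_way_anova(alpha$percent, alpha$condition, alpha$electrode)
  cat("\ntwo-way ANOVA of alpha power change (condition x electrode):\n")
  print(as.data.frame(res), digits = 4)
  utils::write.csv(as.data.frame(res),
                   file.path(out, "anova_erd_alpha.csv"), row.names = FALSE)
  # condition contrast at the peak-ERD electrode
  c3 <- alpha[alpha$electrode == "C3", ]
  tk3 <- tukey_kramer_groups(c3$percent, c3$condition)
  cat("\nTukey-Kramer at C3 (alpha % change):\n")
  print(tk3, digits = 3)
  utils::write.csv(tk3, file.path(out, "tukey_c3_alpha.csv"),
                   row.names = FALSE)
}
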