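#!/usr/bin/env Rscript
# Orientation decoding: one-vs-one linear SVM on standardized trial-level
# population responses, 10-fold stratified cross-validation, per arm
# (baseline/CFS x grating eye), plus the label-permutation chance level.

library(cfspopcode)

resp <- read_response_csv("results/responses.csv")
out <- list()
for (grp in c("monocular", "cfs")) for (eye in c("contra", "ipsi")) {
  d <- build_design(resp, grp, eye)
  dec <- svm_crossval(d$X, d$y, folds = 10, seed = 31)
  lbl <- paste(if (grp == "monocular") "baseline" else "cfs", eye, sep = "_")
  out[[lbl]] <- list(mean_accuracy = dec$mean_accuracy, ci95 = dec$ci95)
  cat(sprintf("%-16s accuracy %5.1f%%  (95%% CI %5.1f-%5.1f)\n", lbl,
              100 * dec$mean_accuracy, 100 * dec$ci95[1],
              100 * dec$ci95[2]))
}
d <- build_design(resp, "monocular", "contra")
pn <- permutation_null_accuracy(d$X, d$y, n_perm = 3, seed = 32)
cat(sprintf("permutation chance %.1f%% (multinomial 95%% band %.1f-%.1f%%)\n",
            100 * pn$mean_accuracy, 100 * pn$band[1], 100 * pn$band[2]))
out$chance <- list(mean_accuracy = pn$mean_accuracy, band = pn$band)
write_report_json(out, "results/decoding.json")
cat("Wrote results/decoding.json\n")
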