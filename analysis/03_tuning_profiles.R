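#!/usr/bin/env Rscript
# Profile every neuron of the simulated recording: preferred orientation
# and SF per viewing condition, Friedman orientation selectivity at
# alpha = 0.01, ODI from rectified peak monocular responses, and the eye
# weights feeding the gain model.

library(cfspopcode)

resp <- read_response_csv("results/responses.csv")
prof <- neuron_profiles(resp)
write.csv(prof, "results/neuron_profiles.csv", row.names = FALSE)

cat(sum(prof$is_tuned), "of", nrow(prof), "neurons orientation-tuned\n")
cat("ODI: ", round(100 * mean(abs(prof$odi) <= 0.2, na.rm = TRUE), 1),
    "% binocular (|ODI| <= 0.2)\n", sep = "")
w <- subgroup_weights(prof)
cat("subgroup mean eye weights (grating / binocular / masker):",
    round(w, 2), "\n")
cat("Wrote results/neuron_profiles.csv\n")
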