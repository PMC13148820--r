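#!/usr/bin/env Rscript
# The two-step OD-dependent gain-control model. Step I fits the
# OD-weighted Gaussian basis jointly to the three baseline subgroup
# curves; Step II freezes those parameters and fits the bandwidth
# inhibition (w^t) and interocular suppression/summation (a N^k, b N^m)
# to the CFS subgroup curves.

library(cfspopcode)

resp <- read_response_csv("results/responses.csv")
prof <- neuron_profiles(resp)
groups <- c("grating_eye_pref", "binocular", "masker_eye_pref")

base_curves <- lapply(groups, function(g)
  bin_population(prof, resp, "monocular", subgroup = g))
cfs_curves <- lapply(groups, function(g)
  bin_population(prof, resp, "cfs", subgroup = g))
w <- subgroup_weights(prof)
N <- subgroup_masker_response(prof, resp)
cat("subgroup eye weights:", round(w, 2), "\n")
cat("subgroup masker responses:", round(N, 3), "\n")

s1 <- step1_fit(base_curves, w, seed = 1)
cat(sprintf("Step I  (A, sigma, B, s) = (%.3f, %.1f, %.3f, %.2f), R2 = %.3f\n",
            s1$params$A, s1$params$sigma, s1$params$B, s1$params$s,
            s1$r_squared))

s2 <- step2_fit(cfs_curves, s1$params, N, w, seed = 1)
cat(sprintf("Step II (t, a, k, b, m) = (%.2f, %.2f, %.2f, %.3f, %.2f), R2 = %.3f\n",
            s2$params$t, s2$params$a_n, s2$params$k, s2$params$b_n,
            s2$params$m, s2$r_squared))

write_report_json(list(
  w_groups = as.list(w), N_groups = as.list(N),
  step1 = c(s1$params[c("A", "sigma", "B", "s")],
            list(r_squared = s1$r_squared)),
  step2 = c(s2$params[c("t", "a_n", "k", "b_n", "m")],
            list(r_squared = s2$r_squared))
), "results/gain_model.json")
cat("Wrote results/gain_model.json\n")
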