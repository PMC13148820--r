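# shared small fixtures, built once per test run

fixture_env <- new.env()

# small noisy synthetic dataset (30 neurons, 6 trials)
small_dataset <- function() {
  if (is.null(fixture_env$small))
    fixture_env$small <- synthetic_dataset(
      30, protocol = cfs_protocol(6), seed = 42)
  fixture_env$small
}

# noise-free twin of the small dataset
small_dataset_clean <- function() {
  if (is.null(fixture_env$small_clean))
    fixture_env$small_clean <- synthetic_dataset(
      30, protocol = cfs_protocol(6), noise_on = FALSE, seed = 42)
  fixture_env$small_clean
}

small_profiles <- function() {
  if (is.null(fixture_env$small_prof))
    fixture_env$small_prof <- neuron_profiles(small_dataset()$responses)
  fixture_env$small_prof
}

# rasterized disc mask of radius r
disc_mask <- function(r, pad = 2) {
  n <- 2 * r + 1 + 2 * pad
  c0 <- r + 1 + pad
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

# response tensor with hand-set per-condition trial values for one neuron.
# mono_fun(orientation, sf, eye) gives the condition mean; each condition
# gets two trials mean -/+ d (sample SD = d * sqrt(2)), identical for the
# two drift directions.
handmade_tensor <- function(mono_fun, d = 0.1 / sqrt(2), n_neurons = 1) {
  protocol <- cfs_protocol(2)
  cd <- protocol$conditions
  vals <- array(0, dim = c(n_neurons, nrow(cd), 2))
  for (j in seq_len(nrow(cd))) {
    mu <- if (cd$group[j] %in% c("monocular", "cfs"))
      mono_fun(cd$orientation[j], cd$sf[j], cd$eye[j])
    else if (cd$group[j] == "binocular")
      mono_fun(cd$orientation[j], cd$sf[j], "contra")
    else 0.1
    vals[, j, 1] <- mu - d
    vals[, j, 2] <- mu + d
  }
  structure(list(values = vals, conditions = cd, trials_per_condition = 2L),
            class = "response_tensor")
}
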