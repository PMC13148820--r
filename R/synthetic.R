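#' Configuration of the synthetic neuron population
#'
#' Defaults emulate a macaque V1 field of view: a unimodal ocular dominance
#' index (ODI) distribution centred at 0 (truncated normal, SD 0.35, so most
#' neurons are binocular), uniform preferred orientations, half of the
#' neurons preferring each of the two spatial frequencies, base-2 Gaussian
#' orientation tuning with half-width-at-half-height near 30 degrees, and
#' trial noise whose SD follows the (Gaussian-shaped) mean tuning:
#' sd = noise_base + noise_gain * mean.
#'
#' @param odi_mean,odi_sd parameters of the truncated-normal ODI
#'   distribution on [-1, 1].
#' @param hwhm_mean,hwhm_sd tuning half-width-at-half-height (degrees).
#' @param amp_mean,amp_sd tuning amplitude (dF/F0), truncated above 0.05.
#' @param baseline untuned response floor (dF/F0).
#' @param sf_atten multiplicative attenuation of the amplitude at the
#'   non-preferred spatial frequency.
#' @param noise_base,noise_gain trial-noise SD curve coefficients.
#' @param w_clip per-neuron eye weights are clipped into
#'   [w_clip, 1 - w_clip] when applying the OD gain, so rare near-monocular
#'   neurons do not dominate subgroup means through w^s with negative s.
#' @param field_px rendered field size (pixels; 850 um at 1.6 um/px).
#' @param soma_radius rendered soma disc radius (pixels).
#' @return a \code{population_config} list.
#' @export
population_config <- function(odi_mean = 0, odi_sd = 0.35,
                              hwhm_mean = 30, hwhm_sd = 3,
                              amp_mean = 0.5, amp_sd = 0.05,
                              baseline = 0.05, sf_atten = 0.5,
                              noise_base = 0.08, noise_gain = 0.10,
                              w_clip = 0.1,
                              field_px = 531, soma_radius = 4) {
  if (odi_sd <= 0 || hwhm_sd < 0 || amp_sd < 0)
    stop("invalid distribution parameters: SDs must be positive")
  if (hwhm_mean <= 0 || amp_mean <= 0)
    stop("invalid distribution parameters: means must be positive")
  as.list(environment())
}

## inverse-CDF sampler for a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Sample a ground-truth neuron population
#'
#' Draws \code{n_neurons} neurons with ODI, preferred orientation and
#' spatial frequency, tuning amplitude/width, baseline, trial-noise
#' parameters and non-overlapping soma positions for image rendering.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param config a \code{\link{population_config}}.
#' @param seed integer seed; the same (config, seed) reproduces the
#'   population exactly.
#' @param place_somas also draw non-overlapping soma positions for image
#'   rendering (set FALSE for large populations that are never rendered).
#' @return data.frame with one row per neuron (class
#'   \code{ground_truth_neurons}).
#' @export
sample_population <- function(n_neurons, config = population_config(),
                              seed = 1, place_somas = TRUE) {
  stopifnot(n_neurons >= 1)
  set.seed(seed)
  odi <- rtruncnorm(n_neurons, config$odi_mean, config$odi_sd, -1, 1)
  pref_ori <- runif(n_neurons, 0, 180)
  pref_sf <- sample(c(3, 6), n_neurons, replace = TRUE)
  hwhm <- pmax(rnorm(n_neurons, config$hwhm_mean, config$hwhm_sd), 5)
  amp <- pmax(rnorm(n_neurons, config$amp_mean, config$amp_sd), 0.05)
  centers <- if (place_somas)
    place_somas(n_neurons, config$field_px, config$soma_radius)
  else matrix(NA_real_, n_neurons, 2)
  neurons <- data.frame(
    neuron_id = seq_len(n_neurons),
    odi_true = odi,
    pref_orientation = wrap_orientation(pref_ori),
    pref_sf = pref_sf,
    tuning_amplitude = amp,
    tuning_hwhm = hwhm,
    baseline_response = config$baseline,
    noise_base = config$noise_base,
    noise_gain = config$noise_gain,
    soma_row = centers[, 1],
    soma_col = centers[, 2],
    soma_radius = config$soma_radius
  )
  attr(neurons, "config") <- config
  class(neurons) <- c("ground_truth_neurons", "data.frame")
  neurons
}

## rejection-sample non-overlapping disc centers on the field
place_somas <- function(n, field_px, radius) {
  min_d2 <- (2 * radius + 2)^2
  centers <- matrix(NA_real_, n, 2)
  margin <- radius + 1
  placed <- 0
  attempts <- 0
  while (placed < n) {
    attempts <- attempts + 1
    if (attempts > 200 * n)
      stop("soma placement impossible without overlap at requested density (",
           n, " somas of radius ", radius, " in ", field_px, " px field)")
    cand <- c(runif(1, margin, field_px - margin),
              runif(1, margin, field_px - margin))
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1
    centers[placed, ] <- cand
  }
  round(centers)
}

## clipped per-neuron eye weight for the grating eye
neuron_eye_weight <- function(neurons, grating_eye, w_clip) {
  w <- eye_weight(neurons$odi_true, grating_eye)
  pmin(pmax(w, w_clip), 1 - w_clip)
}

#' Noise-free mean responses of every neuron to every condition
#'
#' The generative forward model. Monocular responses follow each neuron's
#' eye-weighted base-2 Gaussian tuning (weight w from its ODI, exponent
#' \code{gain$s}); CFS responses apply the bandwidth-inhibition and
#' suppression/summation model to that tuning with the neuron's own masker
#' response (\code{gain$N} scaled by its masker-eye weight gain), so that
#' masker-eye-preferring neurons -- which respond strongly to the masker --
#' are suppressed hardest; binocular responses are the elementwise max of
#' the two monocular responses; masker-only responses equal the same
#' per-neuron masker response.
#'
#' @param neurons \code{ground_truth_neurons}.
#' @param protocol \code{cfs_protocol}.
#' @param gain \code{gain_params} (the scalar \code{N} is used).
#' @return matrix neurons x conditions of mean dF/F0.
#' @export
condition_mean_matrix <- function(neurons, protocol, gain) {
  cfg <- attr(neurons, "config")
  w_clip <- if (is.null(cfg)) 0.1 else cfg$w_clip
  sf_atten <- if (is.null(cfg)) 0.5 else cfg$sf_atten
  conds <- protocol$conditions
  n <- nrow(neurons)
  mu <- matrix(0, n, nrow(conds))
  N <- gain$N[1]
  w_eye <- list(contra = neuron_eye_weight(neurons, "contra", w_clip),
                ipsi = neuron_eye_weight(neurons, "ipsi", w_clip))

  mono_mean <- function(eye, ori, sf) {
    w <- w_eye[[eye]]
    dth <- relative_orientation(neurons$pref_orientation, ori)
    amp <- neurons$tuning_amplitude *
      ifelse(neurons$pref_sf == sf, 1, sf_atten)
    w^gain$s * (amp * 2^(-(dth / neurons$tuning_hwhm)^2) +
                  neurons$baseline_response)
  }
  for (j in seq_len(nrow(conds))) {
    cd <- conds[j, ]
    mu[, j] <- switch(cd$group,
      monocular = mono_mean(cd$eye, cd$orientation, cd$sf),
      cfs = {
        w <- w_eye[[cd$eye]]
        other <- if (cd$eye == "contra") "ipsi" else "contra"
        N_i <- w_eye[[other]]^gain$s * N   # the neuron's own masker response
        dth <- relative_orientation(neurons$pref_orientation, cd$orientation)
        amp <- neurons$tuning_amplitude *
          ifelse(neurons$pref_sf == cd$sf, 1, sf_atten)
        rp <- w^gain$s *
          (amp * 2^(-(dth / (neurons$tuning_hwhm * w^gain$t))^2) +
             neurons$baseline_response)
        rp / (gain$a_n * N_i^gain$k) + gain$b_n * N_i^gain$m
      },
      binocular = pmax(mono_mean("contra", cd$orientation, cd$sf),
                       mono_mean("ipsi", cd$orientation, cd$sf)),
      masker_only = w_eye[[cd$eye]]^gain$s * N
    )
  }
  mu
}

#' Simulate trial-by-trial responses under the full protocol
#'
#' Adds independent Gaussian trial noise around the generative mean of each
#' (neuron, condition); the noise SD follows the orientation-dependent curve
#' sd = noise_base + noise_gain * mean, so variance tuning tracks mean
#' tuning as assumed by the Fisher-information analysis.
#'
#' @param neurons \code{ground_truth_neurons}.
#' @param protocol \code{cfs_protocol}.
#' @param gain \code{gain_params}.
#' @param noise_on if FALSE, trials equal the mean exactly.
#' @param seed integer seed.
#' @return a \code{response_tensor}: list with \code{values} (array neurons
#'   x conditions x trials), \code{conditions}, \code{trials_per_condition}.
#' @export
simulate_trial_responses <- function(neurons, protocol, gain,
                                     noise_on = TRUE, seed = 1) {
  mu <- condition_mean_matrix(neurons, protocol, gain)
  n <- nrow(neurons); C <- ncol(mu); T <- protocol$trials_per_condition
  vals <- array(rep(mu, T), dim = c(n, C, T))
  if (noise_on) {
    set.seed(seed)
    sdv <- pmax(neurons$noise_base + neurons$noise_gain * mu, 1e-6)
    vals <- vals + array(rnorm(n * C * T, sd = rep(sdv, T)),
                         dim = c(n, C, T))
  }
  structure(list(values = vals, conditions = protocol$conditions,
                 trials_per_condition = T),
            class = "response_tensor")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: population + protocol + trial responses + the
#' generative gain parameters, all seed-determined.
#'
#' @param n_neurons population size.
#' @param config \code{\link{population_config}}.
#' @param protocol \code{\link{cfs_protocol}}.
#' @param gain \code{\link{gain_params}}.
#' @param noise_on simulate trial noise?
#' @param seed integer seed (population and noise draw seeds derive from it).
#' @return a \code{synthetic_dataset} list.
#' @export
synthetic_dataset <- function(n_neurons = 300, config = population_config(),
                              protocol = cfs_protocol(),
                              gain = gain_params(), noise_on = TRUE,
                              seed = 1) {
  neurons <- sample_population(n_neurons, config, seed = seed)
  responses <- simulate_trial_responses(neurons, protocol, gain,
                                        noise_on = noise_on,
                                        seed = seed + 1000003L)
  structure(list(neurons = neurons, protocol = protocol,
                 responses = responses, gain = gain, seed = seed),
            class = "synthetic_dataset")
}

#' Render differential images with planted cell bodies
#'
#' One image per condition: each neuron's soma disc carries an intensity
#' equal to that neuron's condition-mean response, on top of zero-mean
#' Gaussian pixel noise. Ground-truth soma masks are returned as a label
#' matrix for detection scoring.
#'
#' @param neurons \code{ground_truth_neurons} (with soma positions).
#' @param responses \code{response_tensor} (condition means are used).
#' @param image_config list with \code{field_px} and \code{bg_sd}.
#' @param seed integer seed for the pixel noise.
#' @return list with \code{images} (field_px x field_px x n_conditions
#'   array), \code{masks} (label matrix, 0 = background) and the config.
#' @export
render_differential_images <- function(neurons, responses,
                                       image_config = list(field_px = 531,
                                                           bg_sd = 0.05),
                                       seed = 1) {
  fp <- image_config$field_px
  bg_sd <- image_config$bg_sd
  mu <- apply(responses$values, c(1, 2), mean)
  C <- ncol(mu)
  masks <- matrix(0L, fp, fp)
  disc_idx <- vector("list", nrow(neurons))
  r <- neurons$soma_radius
  for (i in seq_len(nrow(neurons))) {
    rows <- max(1, neurons$soma_row[i] - r[i]):min(fp, neurons$soma_row[i] + r[i])
    cols <- max(1, neurons$soma_col[i] - r[i]):min(fp, neurons$soma_col[i] + r[i])
    grid <- expand.grid(row = rows, col = cols)
    keep <- (grid$row - neurons$soma_row[i])^2 +
      (grid$col - neurons$soma_col[i])^2 <= r[i]^2
    idx <- grid$row[keep] + (grid$col[keep] - 1L) * fp
    disc_idx[[i]] <- idx
    masks[idx] <- i
  }
  set.seed(seed)
  images <- array(if (bg_sd > 0) rnorm(fp * fp * C, sd = bg_sd) else 0,
                  dim = c(fp, fp, C))
  for (j in seq_len(C)) {
    img <- images[, , j]
    for (i in seq_len(nrow(neurons))) img[disc_idx[[i]]] <- img[disc_idx[[i]]] + mu[i, j]
    images[, , j] <- img
  }
  list(images = images, masks = masks, config = image_config)
}
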