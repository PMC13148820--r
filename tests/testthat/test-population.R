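test_that("population binning reproduces a shared tuning curve exactly", {
  # identical neurons, noise off: every bin traces the single tuning curve
  cfg <- population_config(hwhm_sd = 0, amp_sd = 0)
  neurons <- sample_population(40, cfg, seed = 6)
  neurons$odi_true <- rep(0, 40)            # all binocular, w = 0.5
  neurons$pref_orientation <- seq(0, 175.5, length.out = 40)
  neurons$pref_sf <- rep(3, 40)
  resp <- simulate_trial_responses(neurons, cfs_protocol(2), gain_params(),
                                   noise_on = FALSE, seed = 6)
  prof <- neuron_profiles(resp)
  curve <- bin_population(prof, resp, "monocular", eye = "contra",
                          tuned_only = FALSE)
  w <- 0.5
  expected <- w^gain_params()$s *
    (cfg$amp_mean * 2^(-(curve$bin_center / cfg$hwhm_mean)^2) + cfg$baseline)
  # binning smears each neuron's curve by its off-grid preference offset
  expect_equal(curve$bin_mean, expected, tolerance = 0.05)
  expect_equal(curve$bin_center[which.max(curve$bin_mean)], 0)
  expect_true(all(curve$n > 0))
})

test_that("binned curves are invariant to circular stimulus relabeling", {
  ds <- small_dataset_clean()
  prof <- neuron_profiles(ds$responses)
  curve1 <- bin_population(prof, ds$responses, "monocular")
  # rotate every preferred orientation by +30 degrees: the stimulus grid
  # is unchanged but all relative geometry shifts circularly, so the
  # relative-orientation population curve is identical
  neurons2 <- ds$neurons
  neurons2$pref_orientation <-
    wrap_orientation(ds$neurons$pref_orientation + 30)
  resp2 <- simulate_trial_responses(neurons2, ds$protocol, ds$gain,
                                    noise_on = FALSE, seed = 1)
  prof2 <- neuron_profiles(resp2)
  curve2 <- bin_population(prof2, resp2, "monocular")
  expect_equal(curve2$bin_mean, curve1$bin_mean, tolerance = 1e-10)
})

test_that("the base-2 Gaussian fit recovers exact and noisy parameters", {
  th <- seq(-75, 90, by = 15)
  truth <- list(a = 0.5, theta0 = 0, sigma = 30, b = 0.1)
  y <- truth$a * 2^(-((th - truth$theta0) / truth$sigma)^2) + truth$b
  fit <- fit_population_gaussian(data.frame(bin_center = th, bin_mean = y))
  expect_equal(fit$a, truth$a, tolerance = 1e-8)
  expect_equal(fit$theta0, truth$theta0, tolerance = 1e-8)
  expect_equal(fit$sigma, truth$sigma, tolerance = 1e-8)
  expect_equal(fit$b, truth$b, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # flat curve: amplitude collapses toward zero
  flat <- fit_population_gaussian(data.frame(bin_center = th,
                                             bin_mean = rep(0.2, 12)))
  expect_lt(flat$a, 1e-6)

  # noisy replicates: median amplitude error under 5%
  set.seed(10)
  err <- replicate(300, {
    yn <- y + rnorm(12, sd = 0.05 * truth$a)
    f <- fit_population_gaussian(data.frame(bin_center = th, bin_mean = yn))
    abs(f$a - truth$a) / truth$a
  })
  expect_lt(median(err), 0.05)

  expect_error(fit_population_gaussian(
    data.frame(bin_center = th[1:4], bin_mean = y[1:4])), "bins")
})

test_that("suppression metrics follow the closed-form slope", {
  th <- seq(-75, 90, by = 15)
  mk <- function(a, sigma) fit_population_gaussian(
    data.frame(bin_center = th, bin_mean = a * 2^(-(th / sigma)^2) + 0.05))
  base <- mk(0.6, 30)
  expect_equal(unlist(suppression_metrics(base, base)[1:2]),
               c(amplitude_decrease_pct = 0, slope_decrease_pct = 0),
               tolerance = 1e-6)
  half <- mk(0.3, 30)
  m <- suppression_metrics(base, half)
  expect_equal(m$amplitude_decrease_pct, 50, tolerance = 1e-4)
  expect_equal(m$slope_decrease_pct, 50, tolerance = 1e-4)
  # amplitude halved AND width doubled: slope falls by 75%
  hw <- mk(0.3, 60)
  expect_equal(suppression_metrics(base, hw)$slope_decrease_pct, 75,
               tolerance = 1e-4)
  # analytic maximum slope of the base-2 Gaussian
  fit <- mk(0.5, 25)
  grid <- seq(-90, 90, by = 0.001)
  num_slope <- max(abs(diff(0.5 * 2^(-(grid / 25)^2)) / diff(grid)))
  expect_equal(max_slope(fit), num_slope, tolerance = 1e-5)
  # scale invariance
  m1 <- suppression_metrics(mk(0.6, 30), mk(0.2, 45))
  m2 <- suppression_metrics(mk(1.8, 30), mk(0.6, 45))
  expect_equal(m1$amplitude_decrease_pct, m2$amplitude_decrease_pct,
               tolerance = 1e-6)
  expect_equal(m1$slope_decrease_pct, m2$slope_decrease_pct,
               tolerance = 1e-6)
})

test_that("OD subgroups combine the two grating-eye arms as prescribed", {
  prof <- data.frame(neuron_id = 1:5,
                     odi = c(-0.5, -0.1, 0.1, 0.5, NA))
  g_contra <- split_by_od(prof, "contra")
  g_ipsi <- split_by_od(prof, "ipsi")
  expect_equal(as.character(g_contra[1]), "grating_eye_pref")
  expect_equal(as.character(g_ipsi[1]), "masker_eye_pref")
  expect_equal(as.character(g_contra[4]), "masker_eye_pref")
  expect_equal(as.character(g_ipsi[4]), "grating_eye_pref")
  expect_equal(as.character(g_contra[2:3]), rep("binocular", 2))
  expect_equal(as.character(g_ipsi[2:3]), rep("binocular", 2))
  expect_true(is.na(g_contra[5]))
})

test_that("Fisher information matches the closed form for an analytic neuron", {
  a <- 1; sig <- 30; sd0 <- 0.1
  tensor <- handmade_tensor(function(ori, sf, eye) {
    rel <- relative_orientation(0, ori)
    if (sf == 3) a * 2^(-(rel / sig)^2) else 0.5 * 2^(-(rel / sig)^2)
  }, d = sd0 / sqrt(2))
  prof <- neuron_profiles(tensor)
  grid <- seq(-90, 90, by = 5)
  fi <- fisher_information(prof, tensor, "monocular", eye = "contra",
                           grid = grid, tuned_only = FALSE)
  u <- grid / sig
  fprime <- a * 2^(-u^2) * (-2 * log(2) * u / sig)
  expect_lt(max(abs(fi$curve$info - fprime^2 / sd0^2)), 1e-9)

  # doubling all mean responses at fixed SD quadruples the information
  tensor2 <- handmade_tensor(function(ori, sf, eye) {
    rel <- relative_orientation(0, ori)
    if (sf == 3) 2 * a * 2^(-(rel / sig)^2) else 2^(-(rel / sig)^2)
  }, d = sd0 / sqrt(2))
  fi2 <- fisher_information(neuron_profiles(tensor2), tensor2, "monocular",
                            eye = "contra", grid = grid, tuned_only = FALSE)
  expect_equal(fi2$curve$info, 4 * fi$curve$info, tolerance = 1e-6)

  # adding a constant to all responses leaves the information unchanged
  tensor3 <- handmade_tensor(function(ori, sf, eye) {
    rel <- relative_orientation(0, ori)
    0.7 + if (sf == 3) a * 2^(-(rel / sig)^2) else 0.5 * 2^(-(rel / sig)^2)
  }, d = sd0 / sqrt(2))
  fi3 <- fisher_information(neuron_profiles(tensor3), tensor3, "monocular",
                            eye = "contra", grid = grid, tuned_only = FALSE)
  expect_equal(fi3$curve$info, fi$curve$info, tolerance = 1e-6)

  # flat mean tuning carries no information
  flat <- handmade_tensor(function(ori, sf, eye) 0.5, d = sd0 / sqrt(2))
  fif <- fisher_information(neuron_profiles(flat), flat, "monocular",
                            eye = "contra", grid = grid, tuned_only = FALSE)
  expect_equal(fif$curve$info, rep(0, length(grid)), tolerance = 1e-12)
})
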