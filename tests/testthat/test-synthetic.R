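test_that("population sampling is seed-deterministic and respects bounds", {
  p1 <- sample_population(200, seed = 7)
  p2 <- sample_population(200, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$odi_true >= -1 & p1$odi_true <= 1))
  expect_true(all(p1$pref_orientation >= 0 & p1$pref_orientation < 180))
  expect_true(all(p1$tuning_hwhm > 0))
  expect_true(all(p1$pref_sf %in% c(3, 6)))
  expect_error(sample_population(10, population_config(odi_sd = -1)),
               "invalid distribution")
})

test_that("binocular fraction matches the truncated-normal mass", {
  # analytic mass of N(0, 0.35) truncated to [-1, 1] on [-0.2, 0.2]
  sd <- 0.35
  mass <- (pnorm(0.2, 0, sd) - pnorm(-0.2, 0, sd)) /
    (pnorm(1, 0, sd) - pnorm(-1, 0, sd))
  pop <- sample_population(10000, seed = 3, place_somas = FALSE)
  expect_equal(mean(abs(pop$odi_true) <= 0.2), mass, tolerance = 0.01)
})

test_that("trial simulation is deterministic and unbiased around the mean", {
  ds1 <- synthetic_dataset(20, protocol = cfs_protocol(4), seed = 5)
  ds2 <- synthetic_dataset(20, protocol = cfs_protocol(4), seed = 5)
  expect_identical(ds1$responses$values, ds2$responses$values)
  # noise off: every trial equals the generative mean
  ds0 <- synthetic_dataset(20, protocol = cfs_protocol(4), noise_on = FALSE,
                           seed = 5)
  mu <- condition_mean_matrix(ds0$neurons, ds0$protocol, ds0$gain)
  for (tt in 1:4) expect_equal(ds0$responses$values[, , tt], mu)
})

test_that("empirical trial SD converges to the configured noise curve", {
  cfg <- population_config()
  neurons <- sample_population(2, cfg, seed = 11)
  protocol <- cfs_protocol(10000)
  resp <- simulate_trial_responses(neurons, protocol, gain_params(),
                                   seed = 12)
  mu <- condition_mean_matrix(neurons, protocol, gain_params())
  sd_target <- pmax(cfg$noise_base + cfg$noise_gain * mu, 1e-6)
  sd_emp <- apply(resp$values, c(1, 2), sd)
  expect_true(all(abs(sd_emp / sd_target - 1) < 0.03))
})

test_that("noise-free tuning refits recover each neuron's ground truth", {
  ds <- small_dataset_clean()
  arm <- cfspopcode:::dir_avg_trials(ds$responses, "monocular", "contra")
  cm <- apply(arm$values, c(1, 2), mean)
  cfg <- attr(ds$neurons, "config")
  for (i in c(1, 7, 19)) {
    nr <- ds$neurons[i, ]
    sel <- arm$meta$sf == nr$pref_sf
    rel <- relative_orientation(nr$pref_orientation,
                                arm$meta$orientation[sel])
    curve <- data.frame(bin_center = rel, bin_mean = cm[i, sel])
    fit <- fit_population_gaussian(curve)
    w <- min(max(eye_weight(nr$odi_true, "contra"), cfg$w_clip),
             1 - cfg$w_clip)
    gain <- w^ds$gain$s
    expect_equal(fit$a, gain * nr$tuning_amplitude, tolerance = 1e-6)
    expect_equal(fit$sigma, nr$tuning_hwhm, tolerance = 1e-6)
    expect_equal(fit$b, gain * nr$baseline_response, tolerance = 1e-6)
    expect_equal(fit$theta0, 0, tolerance = 1e-5)
  }
})

test_that("monocular response gain decreases with the grating-eye weight", {
  # a neuron fully preferring the masker eye has the smallest grating-eye
  # gain in the population (the OD weight w^s with s < 0 is monotone)
  cfg <- population_config()
  neurons <- sample_population(5, cfg, seed = 2)
  neurons$odi_true <- c(-0.9, -0.4, 0, 0.4, 0.9)
  neurons$pref_orientation <- rep(45, 5)
  neurons$tuning_amplitude <- rep(0.5, 5)
  neurons$tuning_hwhm <- rep(30, 5)
  neurons$pref_sf <- rep(3, 5)
  mu <- condition_mean_matrix(neurons, cfs_protocol(2), gain_params())
  cd <- cfs_protocol(2)$conditions
  j <- which(cd$group == "monocular" & cd$eye == "contra" &
               cd$orientation == 45 & cd$sf == 3)[1]
  # grating in the contralateral eye: odi = -0.9 prefers it most
  expect_true(all(diff(mu[, j]) < 0))
})

test_that("identity gain parameters make CFS conditions equal monocular", {
  ds <- synthetic_dataset(15, protocol = cfs_protocol(3),
                          gain = gain_params_identity(), noise_on = FALSE,
                          seed = 9)
  cd <- ds$responses$conditions
  v <- ds$responses$values
  for (e in c("contra", "ipsi")) {
    jm <- which(cd$group == "monocular" & cd$eye == e)
    jc <- which(cd$group == "cfs" & cd$eye == e)
    expect_equal(v[, jc, ], v[, jm, ], tolerance = 1e-12)
  }
})

test_that("rendered differential images plant somas of sufficient size", {
  cfg <- population_config(field_px = 150)
  neurons <- sample_population(20, cfg, seed = 8)
  protocol <- cfs_protocol(2)
  resp <- simulate_trial_responses(neurons, protocol, gain_params(),
                                   noise_on = FALSE, seed = 8)
  rend <- render_differential_images(neurons, resp,
                                     image_config = list(field_px = 150,
                                                         bg_sd = 0),
                                     seed = 1)
  # every planted soma exceeds the 25-pixel detection minimum
  expect_true(all(table(rend$masks[rend$masks > 0]) > 25))
  # zero responses + zero noise -> all-zero stack
  resp0 <- resp
  resp0$values[] <- 0
  rend0 <- render_differential_images(neurons, resp0,
                                      image_config = list(field_px = 150,
                                                          bg_sd = 0),
                                      seed = 1)
  expect_true(all(rend0$images == 0))
  # single neuron with unit response: image support equals the soma disc
  one <- neurons[1, ]
  attr(one, "config") <- cfg
  resp1 <- resp0
  resp1$values <- resp0$values[1, , , drop = FALSE] + 1
  rend1 <- render_differential_images(one, resp1,
                                      image_config = list(field_px = 150,
                                                          bg_sd = 0),
                                      seed = 1)
  expect_setequal(which(rend1$images[, , 1] != 0), which(rend1$masks == 1))
})
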