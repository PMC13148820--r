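#' Pipeline configuration
#'
#' A single serializable object holding every knob of a run: data source
#' (synthetic generator settings), stage toggles and per-stage parameters.
#' A run is fully determined by (config, seed).
#'
#' @param n_neurons synthetic population size.
#' @param trials_per_condition trials per condition (10, 12 or 14).
#' @param population \code{\link{population_config}}.
#' @param gain generative \code{\link{gain_params}}.
#' @param noise_on simulate trial noise.
#' @param seed master seed; stage seeds are derived from it.
#' @param do_decode run the SVM decoding stage.
#' @param do_recon run the reconstruction stage (slowest).
#' @param do_roi render differential images and run ROI screening.
#' @param recon list of reconstruction settings (epochs_phase1, burn_in,
#'   eye, lr, rho).
#' @param alpha Friedman significance level.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(n_neurons = 300, trials_per_condition = 12,
                            population = population_config(),
                            gain = gain_params(), noise_on = TRUE,
                            seed = 1, do_decode = TRUE, do_recon = FALSE,
                            do_roi = FALSE,
                            recon = list(epochs_phase1 = 1500,
                                         burn_in = 500, eye = "contra",
                                         lr = 5e-5, rho = 0.85),
                            alpha = 0.01) {
  structure(as.list(environment()), class = "pipeline_config")
}

## the three subgroup labels in fixed order
SUBGROUPS <- c("grating_eye_pref", "binocular", "masker_eye_pref")

#' Empirical subgroup mean eye weights
#'
#' Mean of the per-neuron eye weights over the (neuron, grating-eye arm)
#' pairs combined into each OD subgroup.
#'
#' @param profiles \code{neuron_profiles} (tuned neurons only are used).
#' @return named numeric(3) for grating-eye-preferring, binocular,
#'   masker-eye-preferring groups.
#' @export
subgroup_weights <- function(profiles) {
  pr <- profiles[profiles$is_tuned & is.finite(profiles$odi), ]
  w <- stats::setNames(numeric(3), SUBGROUPS)
  for (g in SUBGROUPS) {
    vals <- c()
    for (e in c("contra", "ipsi")) {
      grp <- split_by_od(pr, e)
      vals <- c(vals, pr[[paste0("w_", e)]][!is.na(grp) & grp == g])
    }
    w[g] <- mean(vals)
  }
  w
}

#' Empirical subgroup masker responses
#'
#' For each OD subgroup, the mean masker-only response over the combined
#' (neuron, arm) pairs, where for a grating-eye-e arm the masker is in the
#' other eye.
#'
#' @param profiles \code{neuron_profiles}.
#' @param responses \code{response_tensor}.
#' @return named numeric(3).
#' @export
subgroup_masker_response <- function(profiles, responses) {
  cd <- responses$conditions
  masker_mean <- function(eye) {
    j <- which(cd$group == "masker_only" & cd$eye == eye)
    rowMeans(responses$values[, j, , drop = TRUE])
  }
  mm <- list(contra = masker_mean("contra"), ipsi = masker_mean("ipsi"))
  pr <- profiles[profiles$is_tuned & is.finite(profiles$odi), ]
  out <- stats::setNames(numeric(3), SUBGROUPS)
  for (g in SUBGROUPS) {
    vals <- c()
    for (e in c("contra", "ipsi")) {
      other <- if (e == "contra") "ipsi" else "contra"
      grp <- split_by_od(pr, e)
      vals <- c(vals, mm[[other]][pr$neuron_id[!is.na(grp) & grp == g]])
    }
    out[g] <- mean(vals)
  }
  out
}

## fit one (baseline, cfs) curve pair and the suppression metrics
fit_curve_pair <- function(curve_base, curve_cfs) {
  fit_base <- fit_population_gaussian(curve_base)
  fit_cfs <- tryCatch(fit_population_gaussian(curve_cfs),
                      error = function(e)
                        structure(list(converged = FALSE), class = "tuning_fit"))
  list(fit_base = fit_base, fit_cfs = fit_cfs,
       metrics = suppression_metrics(fit_base, fit_cfs))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' simulate -> (optional ROI screening on rendered differential images) ->
#' neuron profiling -> population curves and Gaussian fits (overall and
#' per OD subgroup) -> suppression metrics -> Fisher information -> gain
#' model Step I/II -> (optional) SVM decoding -> (optional) reconstruction.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return a nested report list (class \code{pipeline_report}) containing
#'   every computed metric; serialize with \code{\link{write_report_json}}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  protocol <- cfs_protocol(config$trials_per_condition)
  ds <- synthetic_dataset(config$n_neurons, config$population, protocol,
                          config$gain, noise_on = config$noise_on,
                          seed = config$seed)
  report <- list(seed = config$seed, n_neurons = config$n_neurons)

  if (isTRUE(config$do_roi)) {
    rend <- render_differential_images(ds$neurons, ds$responses,
                                       seed = config$seed + 17L)
    rs <- screen_rois(rend$images)
    mt <- match_rois(rs, rend$masks)
    report$roi <- list(n_detected = length(rs$rois),
                       recovered_fraction = mt$recovered_fraction)
  }

  profiles <- neuron_profiles(ds$responses, alpha = config$alpha)
  report$profiles <- list(
    n_tuned = sum(profiles$is_tuned),
    fraction_tuned = mean(profiles$is_tuned),
    fraction_binocular = mean(abs(profiles$odi) <= 0.2, na.rm = TRUE))

  ## overall population curves (arms combined)
  curve_base <- bin_population(profiles, ds$responses, "monocular")
  curve_cfs <- bin_population(profiles, ds$responses, "cfs")
  overall <- fit_curve_pair(curve_base, curve_cfs)
  report$overall <- list(
    amplitude_decrease_pct = overall$metrics$amplitude_decrease_pct,
    slope_decrease_pct = overall$metrics$slope_decrease_pct,
    cfs_unfittable = overall$metrics$cfs_unfittable,
    fit_base = overall$fit_base[c("a", "theta0", "sigma", "b", "r_squared")],
    fit_cfs = if (overall$fit_cfs$converged)
      overall$fit_cfs[c("a", "theta0", "sigma", "b", "r_squared")] else NULL)

  ## subgroup curves and metrics
  report$subgroups <- list()
  sub_curves_base <- list(); sub_curves_cfs <- list()
  for (g in SUBGROUPS) {
    cb <- bin_population(profiles, ds$responses, "monocular", subgroup = g)
    cc <- bin_population(profiles, ds$responses, "cfs", subgroup = g)
    sub_curves_base[[g]] <- cb; sub_curves_cfs[[g]] <- cc
    pair <- tryCatch(fit_curve_pair(cb, cc), error = function(e) NULL)
    report$subgroups[[g]] <- if (is.null(pair)) list(unfittable = TRUE) else
      list(amplitude_decrease_pct = pair$metrics$amplitude_decrease_pct,
           slope_decrease_pct = pair$metrics$slope_decrease_pct,
           cfs_unfittable = pair$metrics$cfs_unfittable,
           a_base = pair$fit_base$a,
           a_cfs = if (pair$fit_cfs$converged) pair$fit_cfs$a else NA_real_)
  }

  ## Fisher information
  fi_base <- fisher_information(profiles, ds$responses, "monocular")
  fi_cfs <- fisher_information(profiles, ds$responses, "cfs")
  report$fisher <- list(baseline_summary = fi_base$summary,
                        cfs_summary = fi_cfs$summary,
                        ratio_pct = 100 * fi_cfs$summary / fi_base$summary)

  ## OD-dependent gain model
  w_groups <- subgroup_weights(profiles)
  N_groups <- subgroup_masker_response(profiles, ds$responses)
  s1 <- step1_fit(sub_curves_base, w_groups, seed = config$seed)
  report$gain_model <- list(w_groups = w_groups, N_groups = N_groups,
                            step1_r2 = s1$r_squared)
  if (s1$converged) {
    s2 <- step2_fit(sub_curves_cfs, s1$params, N_groups, w_groups,
                    seed = config$seed)
    report$gain_model$step2_r2 <- s2$r_squared
    report$gain_model$step1_params <-
      s1$params[c("A", "sigma", "B", "s")]
    if (s2$converged)
      report$gain_model$step2_params <-
        s2$params[c("t", "a_n", "k", "b_n", "m")]
  }

  ## decoding
  if (isTRUE(config$do_decode)) {
    report$decoding <- list()
    for (grp in c("monocular", "cfs")) for (e in c("contra", "ipsi")) {
      dsn <- build_design(ds$responses, grp, e)
      dec <- svm_crossval(dsn$X, dsn$y, seed = config$seed + 31L)
      lbl <- paste(if (grp == "monocular") "baseline" else "cfs", e,
                   sep = "_")
      report$decoding[[lbl]] <- list(mean_accuracy = dec$mean_accuracy,
                                     ci95 = dec$ci95)
    }
  }

  ## reconstruction
  if (isTRUE(config$do_recon)) {
    rc <- config$recon
    rx <- reconstruction_experiment(ds$responses, eye = rc$eye,
                                    epochs_phase1 = rc$epochs_phase1,
                                    burn_in = rc$burn_in,
                                    seed = config$seed + 53L,
                                    lr = rc$lr, rho = rc$rho)
    report$reconstruction <- list(
      stop_epoch = rx$evaluation$stop_epoch,
      median_ssim_baseline = rx$evaluation$baseline$median_ssim,
      median_ssim_cfs = rx$evaluation$cfs$median_ssim)
  }

  class(report) <- "pipeline_report"
  report
}

#' Write trial responses to long-format CSV
#'
#' Columns: neuron_id, cond_id, group, eye, orientation, sf, direction,
#' trial, dff.
#'
#' @param responses a \code{response_tensor}.
#' @param path output CSV path.
#' @export
write_response_csv <- function(responses, path) {
  cd <- responses$conditions
  n <- dim(responses$values)[1]; C <- dim(responses$values)[2]
  T <- dim(responses$values)[3]
  long <- data.frame(
    neuron_id = rep(seq_len(n), times = C * T),
    cond_id = rep(rep(cd$cond_id, each = n), times = T),
    group = rep(rep(cd$group, each = n), times = T),
    eye = rep(rep(cd$eye, each = n), times = T),
    orientation = rep(rep(cd$orientation, each = n), times = T),
    sf = rep(rep(cd$sf, each = n), times = T),
    direction = rep(rep(cd$direction, each = n), times = T),
    trial = rep(seq_len(T), each = n * C),
    dff = as.vector(responses$values))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read trial responses from long-format CSV
#'
#' Validates that the full 242-condition protocol is present; missing
#' condition groups are named in the error.
#'
#' @param path CSV written by \code{\link{write_response_csv}} (or real
#'   data exported to the same layout).
#' @return a \code{response_tensor}.
#' @export
read_response_csv <- function(path) {
  long <- read.csv(path)
  need <- c("neuron_id", "cond_id", "group", "eye", "orientation", "sf",
            "direction", "trial", "dff")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("layout mismatch: missing columns ",
                         paste(miss, collapse = ", "))
  cd <- unique(long[, c("cond_id", "group", "eye", "orientation", "sf",
                        "direction")])
  cd <- cd[order(cd$cond_id), ]
  for (g in c("cfs", "monocular", "binocular", "masker_only")) {
    expected <- c(cfs = 96, monocular = 96, binocular = 48, masker_only = 2)[g]
    got <- sum(cd$group == g)
    if (got != expected)
      stop("layout mismatch: expected ", expected, " ", g,
           " conditions, found ", got)
  }
  n <- max(long$neuron_id); C <- nrow(cd); T <- max(long$trial)
  if (nrow(long) != n * C * T)
    stop("truncated file: ", nrow(long), " rows, expected ", n * C * T)
  vals <- array(NA_real_, dim = c(n, C, T))
  vals[cbind(long$neuron_id, match(long$cond_id, cd$cond_id), long$trial)] <-
    long$dff
  structure(list(values = vals,
                 conditions = data.frame(cd, row.names = NULL),
                 trials_per_condition = T),
            class = "response_tensor")
}

#' Serialize a pipeline report (or any metric list) to JSON
#'
#' @param report a list.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
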