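## bin centers of the 12-bin relative-orientation axis
POP_BIN_CENTERS <- seq(-75, 90, by = 15)

## snap a preferred orientation onto the 15-degree stimulus grid
pref_bin_orientation <- function(pref) {
  wrap_orientation(round(pref / 15) * 15)
}

#' Assign neurons to ocular dominance subgroups for one grating eye
#'
#' Under grating presentation to \code{grating_eye}, neurons with
#' ODI < -0.2 (contralateral-preferring) belong to the grating-eye group
#' when the grating is contralateral and to the masker-eye group when it is
#' ipsilateral, and vice versa for ODI > 0.2; neurons with |ODI| <= 0.2 are
#' binocular under either arm.
#'
#' @param profiles \code{neuron_profiles}.
#' @param grating_eye "contra" or "ipsi".
#' @return factor with levels \code{grating_eye_pref}, \code{binocular},
#'   \code{masker_eye_pref} (NA for neurons without a valid ODI).
#' @export
split_by_od <- function(profiles, grating_eye = c("contra", "ipsi")) {
  grating_eye <- match.arg(grating_eye)
  odi <- profiles$odi
  pref_contra <- odi < -0.2
  pref_ipsi <- odi > 0.2
  grp <- ifelse(!is.finite(odi), NA_character_,
         ifelse(!pref_contra & !pref_ipsi, "binocular",
         ifelse((grating_eye == "contra") == pref_contra,
                "grating_eye_pref", "masker_eye_pref")))
  factor(grp, levels = c("grating_eye_pref", "binocular", "masker_eye_pref"))
}

## contributions of one (neuron set, eye arm): each tuned neuron's 12
## direction-averaged pref-SF condition means, keyed by relative bin.
## For CFS the preferred SF / orientation bin come from the matching
## monocular arm.
arm_contributions <- function(profiles, responses, group, eye, neuron_ids) {
  arm <- dir_avg_trials(responses, group, eye)
  cm <- apply(arm$values, c(1, 2), mean)
  pref_ori <- profiles[[paste0("pref_ori_", eye)]]
  pref_sf <- profiles[[paste0("pref_sf_", eye)]]
  oris <- sort(unique(arm$meta$orientation))
  res <- vector("list", length(neuron_ids))
  for (ii in seq_along(neuron_ids)) {
    i <- neuron_ids[ii]
    sel <- arm$meta$sf == pref_sf[i]
    v <- cm[i, sel]
    names(v) <- arm$meta$orientation[sel]
    v <- v[as.character(oris)]
    rel <- relative_orientation(pref_bin_orientation(pref_ori[i]), oris)
    res[[ii]] <- data.frame(rel = rel, value = unname(v))
  }
  do.call(rbind, res)
}

#' Population orientation tuning curve
#'
#' Orientation-tuned neurons are snapped to 15-degree preference bins; for
#' each presented orientation every neuron contributes its direction-
#' averaged, preferred-SF mean response at the relative orientation
#' (preference bin minus presented orientation, wrapped into (-90, 90]).
#' Contributions sharing a relative orientation are averaged into 12 bins
#' centred at -75..+90 degrees; the SEM is across contributions.
#'
#' @param profiles \code{neuron_profiles}.
#' @param responses \code{response_tensor}.
#' @param group "monocular" (baseline) or "cfs".
#' @param eye grating eye(s): "contra", "ipsi", or both to combine arms.
#' @param subgroup optional OD subgroup (level of \code{\link{split_by_od}});
#'   the matching neurons of each requested arm are combined exactly as the
#'   subgroup rule prescribes.
#' @param tuned_only restrict to Friedman-passing neurons (default TRUE).
#' @return data.frame (class \code{population_curve}) with
#'   \code{bin_center}, \code{bin_mean}, \code{bin_sem}, \code{n}.
#' @export
bin_population <- function(profiles, responses, group = "monocular",
                           eye = c("contra", "ipsi"), subgroup = NULL,
                           tuned_only = TRUE) {
  stopifnot(group %in% c("monocular", "cfs"))
  contrib <- list()
  for (e in eye) {
    ids <- profiles$neuron_id
    if (tuned_only) ids <- ids[profiles$is_tuned]
    if (!is.null(subgroup)) {
      grp <- split_by_od(profiles, e)
      ids <- intersect(ids, profiles$neuron_id[!is.na(grp) & grp == subgroup])
    }
    if (length(ids))
      contrib[[e]] <- arm_contributions(profiles, responses, group, e, ids)
  }
  contrib <- do.call(rbind, contrib)
  out <- data.frame(bin_center = POP_BIN_CENTERS,
                    bin_mean = NA_real_, bin_sem = NA_real_, n = 0L)
  if (!is.null(contrib)) {
    for (b in seq_along(POP_BIN_CENTERS)) {
      v <- contrib$value[contrib$rel == POP_BIN_CENTERS[b]]
      if (length(v)) {
        out$bin_mean[b] <- mean(v)
        out$bin_sem[b] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
        out$n[b] <- length(v)
      }
    }
  }
  class(out) <- c("population_curve", "data.frame")
  out
}

## base-2 Gaussian tuning model and its closed-form maximal slope
gauss2 <- function(theta, a, theta0, sigma, b) {
  a * 2^(-((theta - theta0) / sigma)^2) + b
}

#' Maximal absolute slope of a fitted base-2 Gaussian tuning curve
#'
#' d/dtheta of a * 2^(-((theta-theta0)/sigma)^2) + b attains its maximum
#' magnitude at |theta - theta0| = sigma / sqrt(2 ln 2), where it equals
#' a * sqrt(2 ln 2 / e) / sigma.
#'
#' @param fit a \code{tuning_fit}.
#' @return maximal |dR/dtheta| (dF/F0 per degree).
#' @export
max_slope <- function(fit) {
  fit$a * sqrt(2 * log(2) / exp(1)) / fit$sigma
}

#' Fit the base-2 Gaussian model to a population curve
#'
#' Nonlinear least squares of R(theta) = a * 2^(-((theta - theta0)/sigma)^2)
#' + b with bounds a >= 0, sigma in [1, 180], theta0 in [-90, 90], from
#' multiple starts (sigma in 15/30/60 degrees, theta0 at the empirical
#' argmax and 0). Curves flat to the fitter come back with a ~ 0 or, if no
#' start converges, flagged unfittable.
#'
#' @param curve \code{population_curve} (missing bins are dropped).
#' @param min_bins minimum non-missing bins required.
#' @return list (class \code{tuning_fit}): a, theta0, sigma, b, r_squared,
#'   converged.
#' @export
fit_population_gaussian <- function(curve, min_bins = 6) {
  ok <- is.finite(curve$bin_mean)
  th <- curve$bin_center[ok]; y <- curve$bin_mean[ok]
  if (sum(ok) < min_bins) stop("need at least ", min_bins, " non-missing bins")
  lower <- c(a = 0, theta0 = -90, sigma = 1, b = -Inf)
  upper <- c(a = Inf, theta0 = 90, sigma = 180, b = Inf)
  th_peak <- th[which.max(y)]
  starts <- expand.grid(a = max(y) - min(y), theta0 = unique(c(th_peak, 0)),
                        sigma = c(15, 30, 60), b = min(y))
  resid_fun <- function(p) gauss2(th, p[1], p[2], p[3], p[4]) - y
  best <- multistart_nls(resid_fun, as.matrix(starts), lower, upper)
  if (is.null(best))
    return(structure(list(a = NA_real_, theta0 = NA_real_, sigma = NA_real_,
                          b = NA_real_, r_squared = NA_real_,
                          converged = FALSE), class = "tuning_fit"))
  p <- unname(best$fit$par)
  pred <- gauss2(th, p[1], p[2], p[3], p[4])
  structure(list(a = p[1], theta0 = p[2], sigma = p[3], b = p[4],
                 r_squared = pooled_r2(y, pred), converged = TRUE),
            class = "tuning_fit")
}

#' Amplitude and slope decrease of the CFS curve relative to baseline
#'
#' amplitude_decrease = 100 * (1 - a_cfs / a_base); the slope metric is the
#' closed-form maximal derivative of the fitted base-2 Gaussian
#' (proportional to a / sigma), so slope_decrease = 100 * (1 -
#' (a_cfs/sigma_cfs) / (a_base/sigma_base)). An unfittable CFS curve
#' (flattened tuning with unmeasurable amplitude) reports a 100% amplitude
#' decrease with \code{cfs_unfittable = TRUE} and an undefined slope.
#'
#' @param fit_base,fit_cfs \code{tuning_fit}s of the baseline and CFS
#'   population curves.
#' @return list(amplitude_decrease_pct, slope_decrease_pct, cfs_unfittable).
#' @export
suppression_metrics <- function(fit_base, fit_cfs) {
  stopifnot(fit_base$converged)
  if (!fit_cfs$converged)
    return(list(amplitude_decrease_pct = 100, slope_decrease_pct = NA_real_,
                cfs_unfittable = TRUE))
  list(amplitude_decrease_pct = 100 * (1 - fit_cfs$a / fit_base$a),
       slope_decrease_pct = 100 * (1 - max_slope(fit_cfs) / max_slope(fit_base)),
       cfs_unfittable = FALSE)
}

## per-neuron mean-tuning and SD-tuning samples over relative orientation
neuron_tuning_samples <- function(profiles, responses, group, eye, ids) {
  arm <- dir_avg_trials(responses, group, eye)
  pref_ori <- profiles[[paste0("pref_ori_", eye)]]
  pref_sf <- profiles[[paste0("pref_sf_", eye)]]
  oris <- sort(unique(arm$meta$orientation))
  lapply(ids, function(i) {
    sel <- which(arm$meta$sf == pref_sf[i])
    sel <- sel[order(arm$meta$orientation[sel])]
    m <- arm$values[i, sel, ]           # 12 x trials
    rel <- relative_orientation(pref_bin_orientation(pref_ori[i]), oris)
    data.frame(rel = rel, f = rowMeans(m), s = apply(m, 1, sd))
  })
}

## bounded base-2 Gaussian fit of a 12-point tuning sample; b floored at
## `min_b` (0 for SD tuning)
fit_gauss2_simple <- function(rel, y, min_b = -Inf) {
  ## sigma floored at 10 degrees: tuning sampled every 15 degrees cannot
  ## support a narrower Gaussian, and unbounded widths let trial noise
  ## masquerade as arbitrarily steep (high-information) tuning
  lower <- c(0, -90, 10, min_b)
  upper <- c(Inf, 90, 180, Inf)
  starts <- rbind(c(max(y) - min(y), rel[which.max(y)], 20, max(min(y), min_b)),
                  c(max(y) - min(y), 0, 40, max(min(y), min_b)))
  best <- multistart_nls(function(p) gauss2(rel, p[1], p[2], p[3], p[4]) - y,
                         starts, lower, upper)
  if (is.null(best)) return(NULL)
  as.list(stats::setNames(best$fit$par, c("a", "theta0", "sigma", "b")))
}

#' Population Fisher information over relative orientation
#'
#' Each neuron's mean tuning f_i(theta) and trial-SD tuning sigma_i(theta)
#' (over its 12 relative orientations, preferred SF, directions averaged)
#' are fitted with base-2 Gaussians; the neuron's information is
#' f_i'(theta)^2 / sigma_i(theta)^2 with the fitted SD floored at
#' \code{eps}. The population curve is the mean across neurons, and the
#' summary is its average over |theta| <= 15 degrees.
#'
#' @param profiles \code{neuron_profiles}.
#' @param responses \code{response_tensor}.
#' @param group "monocular" or "cfs".
#' @param eye grating eye(s); arms are pooled neuron-wise.
#' @param grid evaluation grid of relative orientations (degrees).
#' @param eps SD floor (dF/F0).
#' @param tuned_only restrict to tuned neurons.
#' @return list (class \code{fisher_curve}): \code{curve} data.frame
#'   (theta, info), \code{summary} (mean info within 15 degrees),
#'   \code{n_neurons}, \code{n_excluded}.
#' @export
fisher_information <- function(profiles, responses, group = "monocular",
                               eye = c("contra", "ipsi"),
                               grid = seq(-90, 90, by = 1), eps = 1e-3,
                               tuned_only = TRUE) {
  ids <- profiles$neuron_id
  if (tuned_only) ids <- ids[profiles$is_tuned]
  info <- matrix(0, 0, length(grid))
  n_excluded <- 0
  for (e in eye) {
    samples <- neuron_tuning_samples(profiles, responses, group, e, ids)
    for (sm in samples) {
      ff <- fit_gauss2_simple(sm$rel, sm$f)
      fs <- fit_gauss2_simple(sm$rel, sm$s, min_b = 0)
      if (is.null(ff) || is.null(fs)) { n_excluded <- n_excluded + 1; next }
      u <- (grid - ff$theta0) / ff$sigma
      fprime <- ff$a * 2^(-u^2) * (-2 * log(2) * u / ff$sigma)
      sdv <- pmax(gauss2(grid, fs$a, fs$theta0, fs$sigma, fs$b), eps)
      info <- rbind(info, fprime^2 / sdv^2)
    }
  }
  curve <- data.frame(theta = grid, info = if (nrow(info)) colMeans(info) else NA_real_)
  structure(list(curve = curve,
                 summary = mean(curve$info[abs(curve$theta) <= 15]),
                 n_neurons = nrow(info), n_excluded = n_excluded),
            class = "fisher_curve")
}
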