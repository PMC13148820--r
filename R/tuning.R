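#' Per-trial dF/F0 response from raw fluorescence frames
#'
#' Fn is the greatest of the three candidate post-onset window means
#' (frames 5-8, 6-9 or 7-10, 1-based counting from the first post-onset
#' frame); the response is (Fn - F0_bar) / F0_bar, with F0_bar the
#' condition-mean baseline across trials.
#'
#' @param pre_frames the 4 pre-onset frame values of this trial (kept for
#'   interface symmetry; the baseline used is \code{F0_bar}).
#' @param post_frames at least 10 post-onset frame values.
#' @param F0_bar condition-mean baseline fluorescence (> 0).
#' @return scalar dF/F0, or NA if \code{F0_bar <= 0} (neuron invalid).
#' @export
trial_response <- function(pre_frames, post_frames, F0_bar) {
  stopifnot(length(post_frames) >= 10)
  if (!is.finite(F0_bar) || F0_bar <= 0) return(NA_real_)
  wins <- c(mean(post_frames[5:8]), mean(post_frames[6:9]),
            mean(post_frames[7:10]))
  (max(wins) - F0_bar) / F0_bar
}

## direction-averaged trial values: neurons x (eye,sf,ori) x trials.
## For grating group `group` and eye `eye`; trial j of the two opposite
## drift directions are paired and averaged.
dir_avg_trials <- function(responses, group, eye = NULL) {
  cd <- responses$conditions
  sel <- cd$group == group
  if (!is.null(eye)) sel <- sel & cd$eye == eye
  cd <- cd[sel, ]
  vals <- responses$values[, sel, , drop = FALSE]
  key <- interaction(cd$sf, cd$orientation, drop = TRUE)
  ks <- levels(key)
  n <- dim(vals)[1]; T <- dim(vals)[3]
  out <- array(NA_real_, dim = c(n, length(ks), T))
  meta <- data.frame(sf = numeric(length(ks)), orientation = numeric(length(ks)))
  for (i in seq_along(ks)) {
    cols <- which(key == ks[i])
    out[, i, ] <- (vals[, cols[1], ] + vals[, cols[2], ]) / 2
    meta$sf[i] <- cd$sf[cols[1]]
    meta$orientation[i] <- cd$orientation[cols[1]]
  }
  list(values = out, meta = meta)
}

#' Preferred orientation and spatial frequency of one neuron
#'
#' Argmax of the direction-averaged condition means over the 12
#' orientations x 2 spatial frequencies of one viewing condition; ties are
#' broken toward the lowest orientation, then the lowest SF.
#'
#' @param cond_means numeric vector of condition means.
#' @param meta data.frame with \code{orientation} and \code{sf} per entry.
#' @return list(pref_orientation, pref_sf).
#' @export
preferred_condition <- function(cond_means, meta) {
  ord <- order(-cond_means, meta$orientation, meta$sf)
  list(pref_orientation = meta$orientation[ord[1]],
       pref_sf = meta$sf[ord[1]])
}

#' Friedman test of orientation selectivity
#'
#' Trials are blocks and the 12 orientations treatments; the tie-corrected
#' Friedman chi-square (as implemented in \code{stats::friedman.test}) is
#' referred to a chi-square distribution with k - 1 df.
#'
#' @param mat trials x orientations matrix of responses at the preferred SF.
#' @param alpha significance level (0.01 in this pipeline).
#' @return list(statistic, p, is_tuned).
#' @export
friedman_selectivity <- function(mat, alpha = 0.01) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2) stop("need at least 2 trials (blocks)")
  ft <- friedman.test(mat)
  p <- ft$p.value
  stat <- unname(ft$statistic)
  if (!is.finite(stat)) { stat <- 0; p <- 1 }   # all-tied degenerate table
  list(statistic = stat, p = p, is_tuned = is.finite(p) && p < alpha)
}

#' Ocular dominance index from peak monocular responses
#'
#' ODI = (R_i - R_c) / (R_i + R_c); peaks are rectified at zero first so
#' the index stays in [-1, 1] with noisy baselines.
#'
#' @param R_i peak ipsilateral response (dF/F0).
#' @param R_c peak contralateral response (dF/F0).
#' @return ODI in [-1, 1], or NA if both rectified peaks are zero.
#' @export
compute_odi <- function(R_i, R_c) {
  R_i <- pmax(R_i, 0); R_c <- pmax(R_c, 0)
  ifelse(R_i + R_c > 0, (R_i - R_c) / (R_i + R_c), NA_real_)
}

#' Eye weight of a neuron for a given grating eye
#'
#' Linear transform of the ODI into [0, 1]: w = (ODI + 1)/2 when the
#' grating is in the contralateral eye and 1 - (ODI + 1)/2 when
#' ipsilateral. A smaller w means a stronger preference for the eye seeing
#' the grating (ODI > 0 marks ipsilateral preference), so
#' w(contra) + w(ipsi) = 1 for every neuron.
#'
#' @param odi ODI value(s) in [-1, 1].
#' @param grating_eye "contra" or "ipsi".
#' @return eye weight(s) in [0, 1].
#' @export
eye_weight <- function(odi, grating_eye = c("contra", "ipsi")) {
  grating_eye <- match.arg(grating_eye)
  w_contra <- (odi + 1) / 2
  if (grating_eye == "contra") w_contra else 1 - w_contra
}

#' Profile every neuron: preference, selectivity, ODI, eye weights
#'
#' For each neuron and each viewing condition (monocular contra, monocular
#' ipsi, binocular), finds the preferred orientation/SF by argmax of the
#' direction-averaged condition means and runs the Friedman test across the
#' 12 orientations at the preferred SF. A neuron is orientation-tuned if it
#' passes under at least one viewing condition. The ODI uses the rectified
#' peak monocular responses at each arm's own best orientation and SF.
#'
#' @param responses a \code{response_tensor}.
#' @param alpha Friedman significance level.
#' @param viewing_conditions which arms count toward "tuned" (default all
#'   three).
#' @return data.frame (class \code{neuron_profiles}) with one row per
#'   neuron: preferences per arm, Friedman p values, \code{is_tuned},
#'   \code{odi}, \code{w_contra}, \code{w_ipsi}.
#' @export
neuron_profiles <- function(responses, alpha = 0.01,
                            viewing_conditions = c("contra", "ipsi",
                                                   "binocular")) {
  arms <- list(contra = dir_avg_trials(responses, "monocular", "contra"),
               ipsi = dir_avg_trials(responses, "monocular", "ipsi"),
               binocular = dir_avg_trials(responses, "binocular"))
  n <- dim(responses$values)[1]
  out <- data.frame(neuron_id = seq_len(n))
  peak <- list()
  for (a in names(arms)) {
    arm <- arms[[a]]
    cm <- apply(arm$values, c(1, 2), mean)
    po <- numeric(n); ps <- numeric(n); pv <- numeric(n); pk <- numeric(n)
    for (i in seq_len(n)) {
      pref <- preferred_condition(cm[i, ], arm$meta)
      po[i] <- pref$pref_orientation; ps[i] <- pref$pref_sf
      sfsel <- arm$meta$sf == pref$pref_sf
      mat <- t(arm$values[i, sfsel, ])   # trials x 12 orientations
      pv[i] <- friedman_selectivity(mat, alpha)$p
      pk[i] <- max(cm[i, ])
    }
    out[[paste0("pref_ori_", a)]] <- po
    out[[paste0("pref_sf_", a)]] <- ps
    out[[paste0("friedman_p_", a)]] <- pv
    peak[[a]] <- pk
  }
  out$is_tuned <- Reduce(`|`, lapply(viewing_conditions, function(a)
    out[[paste0("friedman_p_", a)]] < alpha))
  out$odi <- compute_odi(peak$ipsi, peak$contra)
  out$w_contra <- eye_weight(out$odi, "contra")
  out$w_ipsi <- eye_weight(out$odi, "ipsi")
  class(out) <- c("neuron_profiles", "data.frame")
  out
}
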