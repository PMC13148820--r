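#' Wrap an orientation into [0, 180)
#'
#' Gratings are unoriented stimuli modulo 180 degrees.
#'
#' @param x orientation(s) in degrees.
#' @return orientation(s) wrapped into [0, 180).
#' @export
wrap_orientation <- function(x) {
  x %% 180
}

#' Signed relative orientation in (-90, 90]
#'
#' Difference between a preferred and a presented orientation, wrapped onto
#' the half-open interval (-90, 90] so that +90 and -90 are identified.
#'
#' @param pref preferred orientation(s), degrees.
#' @param stim presented orientation(s), degrees.
#' @return signed relative orientation(s) in (-90, 90].
#' @export
relative_orientation <- function(pref, stim) {
  d <- (pref - stim) %% 180
  ifelse(d > 90, d - 180, d)
}

#' The 242-condition dichoptic stimulus protocol
#'
#' Builds the full condition table of one recording block: 96 CFS conditions
#' (grating eye x spatial frequency x 12 orientations x 2 drift directions),
#' 96 matching monocular conditions, 48 binocular conditions and 2
#' flashing-masker-only conditions (one per eye). Conditions are ordered
#' CFS, monocular, binocular, masker-only -- the order used by the
#' differential-image ROI screening.
#'
#' @param trials_per_condition trials recorded per condition (10, 12 or 14).
#' @param orientations grating orientations in degrees (default 0..165 in
#'   15-degree steps).
#' @param sfs the two spatial frequencies, cycles/degree.
#' @return an object of class \code{cfs_protocol}: a list with
#'   \code{conditions} (data.frame with columns \code{cond_id, group, eye,
#'   orientation, sf, direction}) and \code{trials_per_condition}.
#' @export
cfs_protocol <- function(trials_per_condition = 12,
                         orientations = seq(0, 165, by = 15),
                         sfs = c(3, 6)) {
  stopifnot(trials_per_condition >= 2, length(orientations) == 12,
            length(sfs) == 2)
  grating <- expand.grid(direction = c(1L, -1L), orientation = orientations,
                         sf = sfs, eye = c("contra", "ipsi"),
                         stringsAsFactors = FALSE)
  grating <- grating[, c("eye", "sf", "orientation", "direction")]
  binoc <- expand.grid(direction = c(1L, -1L), orientation = orientations,
                       sf = sfs, stringsAsFactors = FALSE)
  conds <- rbind(
    data.frame(group = "cfs", grating, stringsAsFactors = FALSE),
    data.frame(group = "monocular", grating, stringsAsFactors = FALSE),
    data.frame(group = "binocular", eye = "both", binoc[, c("sf", "orientation", "direction")],
               stringsAsFactors = FALSE),
    data.frame(group = "masker_only", eye = c("contra", "ipsi"),
               sf = NA_real_, orientation = NA_real_, direction = NA_integer_,
               stringsAsFactors = FALSE)
  )
  conds <- cbind(cond_id = seq_len(nrow(conds)), conds)
  stopifnot(nrow(conds) == 242L)
  structure(list(conditions = conds,
                 trials_per_condition = as.integer(trials_per_condition)),
            class = "cfs_protocol")
}

#' @export
print.cfs_protocol <- function(x, ...) {
  cat("CFS stimulus protocol:", nrow(x$conditions), "conditions x",
      x$trials_per_condition, "trials\n")
  print(table(x$conditions$group))
  invisible(x)
}
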