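## integer translation with zero fill
translate_int <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  sr <- max(1, 1 + dy):min(h, h + dy)
  sc <- max(1, 1 + dx):min(w, w + dx)
  out[sr, sc] <- img[sr - dy, sc - dx]
  out
}

#' Integer-shift motion correction by normalized cross-correlation
#'
#' For each frame, finds the integer (row, col) shift within
#' \code{max_shift} that maximizes the normalized cross-correlation with
#' the reference over the overlap region, and applies it.
#'
#' @param frames a matrix (single frame) or H x W x F array.
#' @param reference reference image, same H x W.
#' @param max_shift largest shift searched in each direction (pixels).
#' @return list with \code{corrected} (same shape as input), \code{shifts}
#'   (F x 2 matrix of applied (row, col) shifts) and \code{flags}
#'   (TRUE where a frame had zero variance and was left unshifted).
#' @export
motion_correct <- function(frames, reference, max_shift = 5) {
  single <- is.matrix(frames)
  if (single) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(all(dim(frames)[1:2] == dim(reference)))
  nf <- dim(frames)[3]
  shifts <- matrix(0L, nf, 2)
  flags <- logical(nf)
  corrected <- frames
  h <- nrow(reference); w <- ncol(reference)
  for (f in seq_len(nf)) {
    fr <- frames[, , f]
    if (sd(fr) == 0) { flags[f] <- TRUE; next }
    best <- -Inf; bdy <- 0L; bdx <- 0L
    for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
      rr <- max(1, 1 + dy):min(h, h + dy)
      cc <- max(1, 1 + dx):min(w, w + dx)
      a <- fr[rr - dy, cc - dx]; b <- reference[rr, cc]
      if (sd(a) == 0 || sd(b) == 0) next
      cr <- stats::cor(as.vector(a), as.vector(b))
      if (cr > best) { best <- cr; bdy <- dy; bdx <- dx }
    }
    shifts[f, ] <- c(bdy, bdx)
    corrected[, , f] <- translate_int(fr, bdy, bdx)
  }
  if (single) corrected <- corrected[, , 1]
  list(corrected = corrected, shifts = shifts, flags = flags)
}

#' Trial-averaged differential image
#'
#' dF = F - F0 per pixel, where F0 is the mean of the 4 frames before
#' stimulus onset and F the mean of the 6th-9th frames after onset
#' (1-based, \code{stim_onset} being the first post-onset frame), averaged
#' across trials.
#'
#' @param trial_frames list (one per trial, >= 5) of H x W x F arrays.
#' @param stim_onset index of the first post-onset frame (>= 5; at least 9
#'   post-onset frames must exist).
#' @return H x W matrix of dF values.
#' @export
compute_differential_image <- function(trial_frames, stim_onset) {
  if (length(trial_frames) < 5) stop("need >= 5 trials")
  nfr <- dim(trial_frames[[1]])[3]
  if (stim_onset < 5) stop("need 4 pre-onset frames")
  if (nfr - stim_onset + 1 < 9) stop("need >= 9 post-onset frames")
  acc <- 0
  for (tf in trial_frames) {
    pre <- apply(tf[, , (stim_onset - 4):(stim_onset - 1), drop = FALSE],
                 c(1, 2), mean)
    post <- apply(tf[, , (stim_onset + 5):(stim_onset + 8), drop = FALSE],
                  c(1, 2), mean)
    acc <- acc + (post - pre)
  }
  acc / length(trial_frames)
}

#' Band-pass (difference-of-Gaussians) filter
#'
#' blur(sigma = low_px) - blur(sigma = high_px); annihilates constants and
#' passes structure between the two scales (cell-body sized blobs).
#'
#' @param image numeric matrix.
#' @param low_px,high_px Gaussian sigmas in pixels, low < high.
#' @return filtered matrix.
#' @export
bandpass_filter <- function(image, low_px = 2, high_px = 10) {
  stopifnot(low_px < high_px)
  ## mirror-pad so the Gaussian kernel never exceeds the image
  p <- 2 * ceiling(3 * high_px) + 2
  h <- nrow(image); w <- ncol(image)
  ri <- c(pmin(p:1, h), seq_len(h), pmax(h - seq_len(p) + 1, 1))
  ci <- c(pmin(p:1, w), seq_len(w), pmax(w - seq_len(p) + 1, 1))
  padded <- image[ri, ci]
  lo <- EBImage::gblur(padded, sigma = low_px)
  hi <- EBImage::gblur(padded, sigma = high_px)
  as.matrix(lo - hi)[p + seq_len(h), p + seq_len(w)]
}

## 8-connected labeling: EBImage::bwlabel plus union-find over diagonal
## label adjacencies
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  h <- nrow(lab); w <- ncol(lab)
  for (d in list(c(1, 1), c(1, -1), c(1, 0), c(0, 1))) {
    a <- lab[seq_len(h - abs(d[1])) + max(d[1], 0),
             seq_len(w - abs(d[2])) + max(d[2], 0)]
    b <- lab[seq_len(h - abs(d[1])) + max(-d[1], 0),
             seq_len(w - abs(d[2])) + max(-d[2], 0)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

## perimeter of a binary mask. "crack": exact boundary-edge count of the
## pixel set. "smoothed": sub-pixel marching-squares contour of the
## Gaussian-blurred mask at the 0.5 level, which removes the staircase
## inflation (a rasterized disc's crack perimeter is 4/pi times the true
## circumference); falls back to crack for shapes too thin to reach 0.5
## after blurring (those are neuropil-like and score low either way).
perimeter_mask <- function(mask, method = c("smoothed", "crack"),
                           sigma = 1) {
  method <- match.arg(method)
  m0 <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m0[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  h <- nrow(m0); w <- ncol(m0)
  crack <- sum(m0[-h, ] & !m0[-1, ]) + sum(m0[-1, ] & !m0[-h, ]) +
    sum(m0[, -w] & !m0[, -1]) + sum(m0[, -1] & !m0[, -w])
  if (method == "crack") return(crack)
  pad <- ceiling(4 * sigma)
  m <- matrix(0, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  m[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1
  sm <- as.matrix(EBImage::gblur(m, sigma = sigma))
  cl <- grDevices::contourLines(seq_len(nrow(sm)), seq_len(ncol(sm)), sm,
                                levels = 0.5)
  if (!length(cl)) return(crack)
  sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}

#' Roundness of an ROI
#'
#' Roundness = sqrt(4 * pi * A) / P with A the pixel count. Two perimeter
#' conventions are provided: \code{"crack"} is the exact boundary-edge
#' count of the pixel set (an L x L square gives exactly 4L, hence
#' roundness sqrt(pi)/2; a 1 x n line gives 2(n + 1)), and
#' \code{"smoothed"} (default) measures the sub-pixel contour of the
#' Gaussian-blurred mask, which removes the systematic 4/pi staircase
#' inflation of rasterized discs so that compact somata score near 1
#' (slightly above 1 is possible for small discs, since the contour of the
#' blurred disc is marginally shorter than the true circumference).
#' Screening uses the smoothed convention; under the raw crack convention
#' even a perfect disc could only reach pi/4, far below the 0.9 criterion.
#'
#' @param pixels integer linear indices of the ROI pixels.
#' @param dim c(nrow, ncol) of the image the indices refer to.
#' @param method perimeter convention.
#' @return dimensionless roundness.
#' @export
roundness <- function(pixels, dim, method = c("smoothed", "crack")) {
  stopifnot(length(pixels) >= 1)
  rows <- (pixels - 1L) %% dim[1] + 1L
  cols <- (pixels - 1L) %/% dim[1] + 1L
  mask <- matrix(FALSE, diff(range(rows)) + 1L, diff(range(cols)) + 1L)
  mask[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
  A <- length(pixels)
  P <- perimeter_mask(mask, method)
  sqrt(4 * pi * A) / P
}

#' Resolve a new candidate ROI against the existing set
#'
#' The overlap area OA is computed against the single existing ROI with the
#' largest overlap. OA/area_new <= 1/4: the candidate stays on its own;
#' 1/4 < OA/area_new <= 3/4: discarded; OA/area_new > 3/4: merged into
#' that ROI (boundary equalities go to the lower rule).
#'
#' @param new_pixels integer linear indices of the candidate.
#' @param label current ROI label matrix (0 = background).
#' @return list(action = "keep_separate" | "discard" | "merge",
#'   target = label merged into or NA, overlap_ratio).
#' @export
resolve_overlap <- function(new_pixels, label) {
  ov <- label[new_pixels]
  ov <- ov[ov > 0]
  if (!length(ov))
    return(list(action = "keep_separate", target = NA_integer_,
                overlap_ratio = 0))
  tab <- table(ov)
  target <- as.integer(names(tab)[which.max(tab)])
  ratio <- max(tab) / length(new_pixels)
  action <- if (ratio <= 1 / 4) "keep_separate"
            else if (ratio <= 3 / 4) "discard" else "merge"
  list(action = action, target = target, overlap_ratio = as.numeric(ratio))
}

#' Sequential differential-image ROI screening
#'
#' Processes the differential images in protocol order (CFS, monocular,
#' binocular, masker-only), twice. For each image, pixels of already-
#' accepted ROIs are set to the image mean, the image is band-pass
#' filtered, pixels above mean + sd_k * SD of the filtered image are kept,
#' and 8-connected components larger than \code{min_area} become
#' candidates, each resolved against the existing set by
#' \code{\link{resolve_overlap}}. After both passes, ROIs failing the area
#' or roundness criterion are dropped.
#'
#' @param diff_images H x W x C array (or list of matrices) in screening
#'   order.
#' @param sd_k threshold in SDs above the filtered-image mean.
#' @param min_area minimum component area, pixels (strict >).
#' @param passes number of full passes over the stack.
#' @param low_px,high_px band-pass sigmas.
#' @param roundness_min minimum roundness of a final ROI (strict >);
#'   smoothed-perimeter convention.
#' @return a \code{roi_set}: list with \code{rois} (list of pixel index
#'   vectors), \code{label} (matrix), \code{dim}, \code{provenance}
#'   (first-detection image index per ROI).
#' @export
screen_rois <- function(diff_images, sd_k = 3, min_area = 25, passes = 2,
                        low_px = 2, high_px = 10, roundness_min = 0.9) {
  if (is.list(diff_images))
    diff_images <- array(unlist(diff_images),
                         dim = c(dim(diff_images[[1]]), length(diff_images)))
  if (length(dim(diff_images)) != 3 || dim(diff_images)[3] < 1)
    stop("empty differential-image stack")
  h <- dim(diff_images)[1]; w <- dim(diff_images)[2]
  L <- matrix(0L, h, w)
  rois <- list()
  first_seen <- integer()
  for (pass in seq_len(passes)) {
    for (j in seq_len(dim(diff_images)[3])) {
      img <- diff_images[, , j]
      if (length(rois)) img[L > 0] <- mean(img)
      f <- bandpass_filter(img, low_px, high_px)
      thr <- mean(f) + sd_k * sd(f)
      mask <- f > thr
      if (!any(mask)) next
      lab <- label8(mask)
      pixlist <- split(which(lab > 0), lab[lab > 0])
      pixlist <- pixlist[lengths(pixlist) > min_area]
      if (!length(pixlist)) next
      pixlist <- pixlist[order(-lengths(pixlist))]
      for (pix in pixlist) {
        res <- resolve_overlap(pix, L)
        if (res$action == "discard") next
        if (res$action == "keep_separate") {
          new_pix <- pix[L[pix] == 0]
          if (!length(new_pix)) next
          id <- length(rois) + 1L
          rois[[id]] <- new_pix
          L[new_pix] <- id
          first_seen[id] <- j + (pass - 1L) * dim(diff_images)[3]
        } else {                         # merge
          add <- pix[L[pix] == 0]
          rois[[res$target]] <- c(rois[[res$target]], add)
          L[add] <- res$target
        }
      }
    }
  }
  ## final area + roundness filter
  keep <- vapply(rois, function(p)
    length(p) > min_area &&
      roundness(p, c(h, w), "smoothed") > roundness_min, logical(1))
  rois <- rois[keep]
  first_seen <- first_seen[keep]
  L <- matrix(0L, h, w)
  for (id in seq_along(rois)) L[rois[[id]]] <- id
  structure(list(rois = rois, label = L, dim = c(h, w),
                 provenance = data.frame(roi_id = seq_along(rois),
                                         first_image = first_seen)),
            class = "roi_set")
}

#' Summary table of an ROI set
#'
#' @param rs a \code{roi_set}.
#' @return data.frame with roi_id, area, perimeter (smoothed), roundness,
#'   centroid_row, centroid_col.
#' @export
roi_table <- function(rs) {
  do.call(rbind, lapply(seq_along(rs$rois), function(id) {
    p <- rs$rois[[id]]
    rows <- (p - 1L) %% rs$dim[1] + 1L
    cols <- (p - 1L) %/% rs$dim[1] + 1L
    rnd <- roundness(p, rs$dim, "smoothed")
    data.frame(roi_id = id, area = length(p),
               perimeter = sqrt(4 * pi * length(p)) / rnd,
               roundness = rnd,
               centroid_row = mean(rows), centroid_col = mean(cols))
  }))
}

#' Match detected ROIs to ground-truth soma masks by IoU
#'
#' @param rs a \code{roi_set}.
#' @param truth_label ground-truth label matrix (from
#'   \code{\link{render_differential_images}}).
#' @param iou_min IoU above which a soma counts as recovered.
#' @return list(recovered_fraction, matches data.frame).
#' @export
match_rois <- function(rs, truth_label, iou_min = 0.5) {
  truth_ids <- setdiff(unique(as.vector(truth_label)), 0L)
  rows <- lapply(truth_ids, function(tid) {
    tp <- which(truth_label == tid)
    best <- 0; best_roi <- NA_integer_
    cand <- setdiff(unique(rs$label[tp]), 0L)
    for (rid in cand) {
      rp <- rs$rois[[rid]]
      iou <- length(intersect(tp, rp)) / length(union(tp, rp))
      if (iou > best) { best <- iou; best_roi <- rid }
    }
    data.frame(truth_id = tid, roi_id = best_roi, iou = best)
  })
  matches <- do.call(rbind, rows)
  list(recovered_fraction = mean(matches$iou > iou_min), matches = matches)
}

#' Write an image stack to multi-page TIFF
#'
#' Pixel values are affinely mapped to [0, 1] (32-bit float pages), with
#' the mapping recorded so stacks round-trip losslessly via
#' \code{\link{read_image_stack}}.
#'
#' @param images H x W x N array (or a single matrix).
#' @param path output .tif path.
#' @return invisibly, the (offset, scale) mapping used.
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1))
  rng <- range(images)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(images)[3]), function(j)
    (images[, , j] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(offset = rng[1], scale = scale)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(meta)
}

#' Read an image stack written by \code{\link{write_image_stack}}
#'
#' @param path .tif path (the sidecar .json restores the value mapping;
#'   without it, values stay in [0, 1]).
#' @return H x W x N array.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    arr <- arr * meta$scale + meta$offset
  }
  arr
}
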