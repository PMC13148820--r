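#' Render a noise-free circular square-wave grating
#'
#' The reconstruction target: a 70 x 70 image of a square-wave grating at
#' the given orientation and spatial frequency inside a circular envelope
#' (the image spans \code{span_deg} degrees of visual angle), bright/dark
#' bars at 1/0 and mean gray 0.5 outside the aperture. Phase 0, no
#' anti-aliasing: the rendering is a fixture convention, not a display
#' model.
#'
#' @param orientation grating orientation, degrees.
#' @param sf spatial frequency, cycles/degree.
#' @param size image side, pixels.
#' @param span_deg visual angle spanned by the image, degrees.
#' @return size x size matrix with values in [0, 1].
#' @export
render_grating <- function(orientation, sf, size = 70, span_deg = 1) {
  px <- seq_len(size) - (size + 1) / 2
  gx <- matrix(px, size, size)
  gy <- t(gx)
  phi <- (orientation + 90) * pi / 180        # modulation axis
  d <- (gx * cos(phi) + gy * sin(phi)) * span_deg / size
  img <- ifelse(sin(2 * pi * sf * d) >= 0, 1, 0)
  img[gx^2 + gy^2 > (size / 2)^2] <- 0.5
  img
}

#' Initialize a reconstruction model
#'
#' Embedding (n x d_model), Q/K/V projections (d_model x d_model),
#' per-neuron unembedding (n x d_model) and an affine feedforward map
#' n -> out_dim (one linear layer, no activation). Weights are uniform in
#' +/- 1/sqrt(fan_in), seed-controlled.
#'
#' @param n_neurons number of input neurons (tokens).
#' @param d_model embedding dimension (2).
#' @param d_k key dimension used in the attention scaling (= d_model).
#' @param out_dim output pixels (4900 = 70 x 70).
#' @param seed integer seed.
#' @return list of weights (class \code{recon_model}).
#' @export
recon_model <- function(n_neurons, d_model = 2, d_k = d_model,
                        out_dim = 4900, seed = 1) {
  set.seed(seed)
  u <- function(nr, nc, fan) matrix(runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
  structure(list(Wemb = u(n_neurons, d_model, 1),
                 WQ = u(d_model, d_model, d_model),
                 WK = u(d_model, d_model, d_model),
                 WV = u(d_model, d_model, d_model),
                 Wunemb = u(n_neurons, d_model, d_model),
                 Wff = u(n_neurons, out_dim, n_neurons),
                 bff = rep(0, out_dim), dk = d_k),
            class = "recon_model")
}

#' Reference forward pass (pure R, single sample)
#'
#' Slow but transparent; the compiled batch forward is cross-checked
#' against this implementation.
#'
#' @param model a \code{recon_model}.
#' @param x input response vector, length n_neurons.
#' @return list(image = 70x70 matrix (or out_dim vector reshaped),
#'   attention = n x n attention map).
#' @export
recon_forward <- function(model, x) {
  M <- model$Wemb * x
  Q <- M %*% model$WQ; K <- M %*% model$WK; V <- M %*% model$WV
  S <- Q %*% t(K) / sqrt(model$dk)
  E <- exp(S - apply(S, 1, max))
  A <- E / rowSums(E)
  R2 <- A %*% V
  u <- rowSums(R2 * model$Wunemb)
  y <- drop(crossprod(model$Wff, u)) + model$bff
  side <- round(sqrt(length(y)))
  img <- if (side * side == length(y)) matrix(y, side, side) else y
  list(image = img, attention = A, output = y)
}

#' Batch prediction (compiled forward)
#'
#' @param model a \code{recon_model}.
#' @param X samples x neurons matrix.
#' @return samples x out_dim matrix of reconstructed pixel vectors.
#' @export
recon_predict <- function(model, X) {
  recon_forward_cpp(unclass(model), X)
}

#' Augment a response dataset for reconstruction training
#'
#' Draws \code{factor} times the original sample count from per-neuron,
#' per-condition normal distributions (mean and SD of the original trials
#' of that condition), then min-max normalizes each neuron to [0, 1] over
#' the augmented set and reserves \code{val_frac} of it for validation.
#' Zero-SD neurons yield degenerate draws equal to their mean.
#'
#' @param X original samples x neurons matrix.
#' @param cond data.frame with one row per sample (orientation, sf).
#' @param factor augmentation factor.
#' @param val_frac validation fraction of the augmented set.
#' @param seed integer seed.
#' @return list(X (normalized augmented), cond, train_idx, val_idx,
#'   norm = list(lo, hi) per-neuron normalization used).
#' @export
augment_dataset <- function(X, cond, factor = 4, val_frac = 0.06, seed = 1) {
  set.seed(seed)
  key <- interaction(cond$orientation, cond$sf, drop = TRUE)
  Xa <- matrix(NA_real_, nrow(X) * factor, ncol(X))
  conda <- cond[rep(seq_len(nrow(cond)), factor), , drop = FALSE]
  r <- 0
  for (rep_i in seq_len(factor)) {
    for (i in seq_len(nrow(X))) {
      rows <- which(key == key[i])
      mu <- colMeans(X[rows, , drop = FALSE])
      sdv <- apply(X[rows, , drop = FALSE], 2, sd)
      r <- r + 1
      Xa[r, ] <- rnorm(ncol(X), mu, ifelse(is.finite(sdv), sdv, 0))
    }
  }
  lo <- apply(Xa, 2, min); hi <- apply(Xa, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  Xa <- sweep(sweep(Xa, 2, lo), 2, rng, "/")
  n_val <- floor(val_frac * nrow(Xa))
  val_idx <- sample(nrow(Xa), n_val)
  list(X = Xa, cond = conda, train_idx = setdiff(seq_len(nrow(Xa)), val_idx),
       val_idx = val_idx, norm = list(lo = lo, hi = hi, rng = rng))
}

#' Train a reconstruction model (full-batch RMSprop)
#'
#' Minimizes the MSE between reconstructed and noise-free target images;
#' per-epoch validation MSE is recorded as the learning curve.
#'
#' @param model a \code{recon_model}.
#' @param X_train,T_train training inputs (S x n) and flattened targets
#'   (S x out_dim).
#' @param X_val,T_val validation split (may have 0 rows).
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param rho RMSprop smoothing factor.
#' @return list(model, train_loss, val_loss).
#' @export
train_recon <- function(model, X_train, T_train, X_val, T_val,
                        epochs, lr = 5e-5, rho = 0.85) {
  out <- recon_train_cpp(unclass(model), X_train, T_train, X_val, T_val,
                         as.integer(epochs), lr, rho)
  model[names(out$params)] <- out$params
  model$bff <- drop(model$bff)
  list(model = model, train_loss = drop(out$train_loss),
       val_loss = drop(out$val_loss))
}

#' Two-plateau sigmoid fit and 75%-decrease stop point
#'
#' Fits loss(t) = A - C / (1 + exp(k (b - t))) to the validation-loss curve
#' with the first \code{burn_in} epochs discarded (t counted from
#' \code{burn_in}), and returns the epoch at which the fitted loss has
#' completed 75% of its total decrease C: stop = b + ln(3)/k, at which the
#' fitted loss equals A - 0.75 C.
#'
#' @param losses per-epoch validation losses (epoch 1 = first epoch).
#' @param burn_in epochs discarded before fitting (500 at full scale).
#' @return list(A, C, k, b, stop_rel (= b + ln(3)/k, in discarded-origin
#'   epochs), stop_epoch (absolute epoch), r_squared).
#' @export
fit_stop_point <- function(losses, burn_in = 500) {
  stopifnot(length(losses) > burn_in + 10)
  l <- losses[(burn_in + 1):length(losses)]
  if (l[length(l)] >= l[1])
    stop("stop-point undefined: validation loss is non-decreasing")
  t <- seq_along(l)
  sig <- function(p) p[1] - p[2] / (1 + exp(p[3] * (p[4] - t)))
  lower <- c(A = -Inf, C = 1e-12, k = 1e-5, b = -Inf)
  upper <- c(A = Inf, C = Inf, k = 1, b = Inf)
  rng <- max(l) - min(l)
  b0 <- t[which.min(abs(l - (max(l) + min(l)) / 2))]
  starts <- as.matrix(expand.grid(A = max(l), C = max(rng, 1e-10),
                                  k = c(0.002, 0.01, 0.05, 0.2),
                                  b = c(b0, length(t) / 2)))
  best <- multistart_nls(function(p) sig(p) - l, starts, lower, upper)
  if (is.null(best)) stop("stop-point undefined: sigmoid fit did not converge")
  p <- unname(best$fit$par)
  if (p[3] <= 0) stop("stop-point undefined: non-decreasing fit (k <= 0)")
  stop_rel <- p[4] + log(3) / p[3]
  list(A = p[1], C = p[2], k = p[3], b = p[4], stop_rel = stop_rel,
       stop_epoch = burn_in + stop_rel, r_squared = pooled_r2(l, sig(p)))
}

#' Structural similarity index (global statistics)
#'
#' SSIM(x, y) = ((2 mu_x mu_y + c1)(2 sigma_xy + c2)) /
#' ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2)) computed over the
#' whole image (single window); population moments. With L = 1,
#' c1 = (0.01 L)^2 and c2 = (0.03 L)^2.
#'
#' @param x,y images (same shape).
#' @param c1,c2 stability constants.
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(x, y, c1 = 1e-4, c2 = 9e-4) {
  stopifnot(length(x) == length(y), c1 > 0, c2 > 0)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

## per-sample flattened target matrix for a design
target_matrix <- function(cond, size = 70, span_deg = 1) {
  key <- interaction(cond$orientation, cond$sf, drop = TRUE)
  imgs <- lapply(levels(key), function(kk) {
    i <- which(key == kk)[1]
    as.vector(render_grating(cond$orientation[i], cond$sf[i], size, span_deg))
  })
  do.call(rbind, imgs)[as.integer(key), , drop = FALSE]
}

## assemble one arm (inputs, targets, augmented split) for reconstruction
prepare_recon_arm <- function(responses, group, eye, factor = 4,
                              val_frac = 0.06, size = 70, seed = 1) {
  ds <- build_design(responses, group, eye)
  cond <- data.frame(orientation = as.numeric(as.character(ds$y)),
                     sf = ds$sf)
  aug <- augment_dataset(ds$X, cond, factor, val_frac, seed)
  X_orig <- sweep(sweep(ds$X, 2, aug$norm$lo), 2, aug$norm$rng, "/")
  list(aug = aug, X_orig = X_orig, cond_orig = cond,
       T_aug = target_matrix(aug$cond, size),
       T_orig = target_matrix(cond, size))
}

#' Retrain baseline and CFS models to a common epoch and score SSIM
#'
#' The stop epoch estimated from the baseline arm's learning curve governs
#' both retrainings (fresh weight initializations). SSIM is computed on
#' the original, non-augmented samples against their noise-free targets;
#' the per-arm medians summarize performance.
#'
#' @param arms list with elements \code{baseline} and \code{cfs}, each from
#'   \code{prepare_recon_arm} (possibly with arms of both eyes pooled).
#' @param stop_epoch common training epoch count.
#' @param seed seed for the fresh initializations.
#' @param lr,rho optimizer settings.
#' @return list (class \code{recon_evaluation}): per-arm SSIM vectors,
#'   medians, stop_epoch.
#' @export
retrain_and_evaluate <- function(arms, stop_epoch, seed = 1, lr = 5e-5,
                                 rho = 0.85) {
  out <- list(stop_epoch = stop_epoch)
  for (a in names(arms)) {
    arm <- arms[[a]]
    model <- recon_model(ncol(arm$aug$X), seed = seed + match(a, names(arms)))
    tr <- train_recon(model,
                      arm$aug$X[arm$aug$train_idx, , drop = FALSE],
                      arm$T_aug[arm$aug$train_idx, , drop = FALSE],
                      arm$aug$X[arm$aug$val_idx, , drop = FALSE],
                      arm$T_aug[arm$aug$val_idx, , drop = FALSE],
                      epochs = max(1, round(stop_epoch)), lr = lr, rho = rho)
    Y <- recon_predict(tr$model, arm$X_orig)
    scores <- vapply(seq_len(nrow(Y)), function(i)
      ssim(Y[i, ], arm$T_orig[i, ]), numeric(1))
    out[[a]] <- list(ssim = scores, median_ssim = median(scores))
  }
  class(out) <- "recon_evaluation"
  out
}

#' Full two-phase reconstruction experiment for one grating eye
#'
#' Phase 1 trains baseline (monocular) and CFS models on augmented data
#' for \code{epochs_phase1} epochs; the stop point is estimated from the
#' baseline validation curve (sigmoid fit after \code{burn_in} epochs) and
#' clamped to the trained range; phase 2 retrains both models from scratch
#' up to that epoch and scores SSIM on the original samples.
#'
#' @param responses a \code{response_tensor}.
#' @param eye grating eye.
#' @param epochs_phase1 phase-1 epochs.
#' @param burn_in epochs discarded before the sigmoid fit.
#' @param seed integer seed.
#' @param lr,rho optimizer settings.
#' @param factor,val_frac augmentation settings.
#' @return list: \code{stop_fit}, \code{evaluation}
#'   (\code{\link{retrain_and_evaluate}} result), \code{curves} (phase-1
#'   validation losses per arm).
#' @export
reconstruction_experiment <- function(responses, eye = "contra",
                                      epochs_phase1 = 1500, burn_in = 500,
                                      seed = 1, lr = 5e-5, rho = 0.85,
                                      factor = 4, val_frac = 0.06) {
  arms <- list(
    baseline = prepare_recon_arm(responses, "monocular", eye, factor,
                                 val_frac, seed = seed),
    cfs = prepare_recon_arm(responses, "cfs", eye, factor, val_frac,
                            seed = seed + 1))
  curves <- list()
  for (a in names(arms)) {
    model <- recon_model(ncol(arms[[a]]$aug$X), seed = seed + 10 + match(a, names(arms)))
    tr <- train_recon(model,
                      arms[[a]]$aug$X[arms[[a]]$aug$train_idx, , drop = FALSE],
                      arms[[a]]$T_aug[arms[[a]]$aug$train_idx, , drop = FALSE],
                      arms[[a]]$aug$X[arms[[a]]$aug$val_idx, , drop = FALSE],
                      arms[[a]]$T_aug[arms[[a]]$aug$val_idx, , drop = FALSE],
                      epochs = epochs_phase1, lr = lr, rho = rho)
    curves[[a]] <- tr$val_loss
  }
  stop_fit <- fit_stop_point(curves$baseline, burn_in = burn_in)
  stop_epoch <- min(max(round(stop_fit$stop_epoch), burn_in + 1),
                    epochs_phase1)
  evaluation <- retrain_and_evaluate(arms, stop_epoch, seed = seed + 100,
                                     lr = lr, rho = rho)
  list(stop_fit = stop_fit, evaluation = evaluation, curves = curves)
}
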