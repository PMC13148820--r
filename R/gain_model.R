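#' Parameters of the OD-dependent gain-control model
#'
#' Bundles the Step-I basis parameters (A, sigma, B, s), the Step-II
#' interocular suppression/summation parameters (t, a_n, k, b_n, m) and the
#' masker response N. Step I describes the baseline (monocular) population
#' orientation tuning of an ocular-dominance subgroup as an OD-weighted
#' Gaussian; Step II describes how a flashing masker in the other eye
#' broadens the tuning (w^t bandwidth factor), divisively suppresses it
#' (a_n * N^k) and adds a binocular summation floor (b_n * N^m).
#'
#' The basis amplitude \code{A} and minimal response \code{B} are in dF/F0
#' units; \code{sigma} is the e-folding width in degrees of the natural-base
#' Gaussian basis (for a base-2 tuning of half-width-at-half-height h,
#' sigma = h / sqrt(log(2))). The exponent \code{s} maps the eye weight w
#' (larger w = stronger preference for the unstimulated/masker eye) onto a
#' response gain; a negative \code{s} makes neurons preferring the
#' stimulated eye respond more, which is the physiological regime.
#'
#' @param A basis amplitude (dF/F0).
#' @param sigma basis width (degrees), natural-base Gaussian.
#' @param B basis minimal response (dF/F0).
#' @param s eye-weight exponent.
#' @param t bandwidth-inhibition exponent (Step II).
#' @param a_n suppression scale (Step II).
#' @param k suppression exponent (Step II).
#' @param b_n summation scale (Step II).
#' @param m summation exponent (Step II).
#' @param N masker response (dF/F0); scalar (generator) or one value per
#'   subgroup (fitting).
#' @return a \code{gain_params} list.
#' @export
gain_params <- function(A = 0.5, sigma = 30 / sqrt(log(2)), B = 0.05,
                        s = -1, t = 0.4, a_n = 20, k = 1, b_n = 0.3, m = 1,
                        N = 0.3) {
  stopifnot(is.numeric(A), is.numeric(sigma), sigma > 0, is.numeric(B),
            is.numeric(s), is.numeric(t), is.numeric(a_n), is.numeric(k),
            is.numeric(b_n), is.numeric(m), is.numeric(N), all(N >= 0))
  if (any(a_n * N^k == 0))
    stop("degenerate suppression: a_n * N^k == 0 (a_n = ", a_n,
         ", k = ", k, ", N = ", paste(N, collapse = ","), ")")
  structure(list(A = A, sigma = sigma, B = B, s = s, t = t, a_n = a_n,
                 k = k, b_n = b_n, m = m, N = N),
            class = "gain_params")
}

#' Identity-limit gain parameters
#'
#' Step-II parameters that make the CFS prediction collapse onto the
#' baseline prediction: no bandwidth change (t = 0), unit divisive gain
#' (a_n * N^k = 1) and no summation floor (b_n = 0).
#'
#' @inheritParams gain_params
#' @export
gain_params_identity <- function(A = 0.5, sigma = 30 / sqrt(log(2)),
                                 B = 0.05, s = -1, N = 0.3) {
  gain_params(A = A, sigma = sigma, B = B, s = s,
              t = 0, a_n = 1, k = 0, b_n = 0, m = 1, N = N)
}

#' OD-weighted Gaussian basis (baseline population tuning)
#'
#' R(theta) = w^s * (A * exp(-(theta/sigma)^2) + B).
#'
#' @param theta relative orientation(s), degrees.
#' @param w eye weight in (0, 1].
#' @param params list with elements A, sigma, B, s (a \code{gain_params}
#'   works).
#' @return predicted response(s), vectorized over \code{theta}.
#' @export
eq1_forward <- function(theta, w, params) {
  stopifnot(all(w > 0 | params$s == round(params$s)), all(w <= 1))
  w^params$s * (params$A * exp(-(theta / params$sigma)^2) + params$B)
}

#' CFS prediction: bandwidth inhibition + interocular suppression/summation
#'
#' R'(theta) = w^s * (A * exp(-(theta/(sigma * w^t))^2) + B), then
#' R_CFS = R' / (a_n * N^k) + b_n * N^m.
#'
#' @param theta relative orientation(s), degrees.
#' @param w eye weight in (0, 1].
#' @param params list with A, sigma, B, s, t, a_n, k, b_n, m.
#' @param N masker response (dF/F0), scalar.
#' @return predicted CFS response(s).
#' @export
eq23_forward <- function(theta, w, params, N = params$N) {
  denom <- params$a_n * N^params$k
  if (any(denom == 0))
    stop("a_n * N^k is zero (a_n = ", params$a_n, ", k = ", params$k,
         ", N = ", N, ")")
  rp <- w^params$s *
    (params$A * exp(-(theta / (params$sigma * w^params$t))^2) + params$B)
  rp / denom + params$b_n * N^params$m
}

## pooled R^2 of stacked predictions against stacked observations
pooled_r2 <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  1 - sum((obs[ok] - pred[ok])^2) / sum((obs[ok] - mean(obs[ok]))^2)
}

## stack a list of population curves (one per subgroup) into a long frame
stack_curves <- function(curves, w_groups, N_groups = NULL) {
  stopifnot(length(curves) == length(w_groups))
  out <- do.call(rbind, lapply(seq_along(curves), function(g) {
    cv <- curves[[g]]
    data.frame(theta = unname(cv$bin_center), y = unname(cv$bin_mean),
               w = unname(w_groups[g]),
               N = if (is.null(N_groups)) NA_real_ else unname(N_groups[g]),
               group = g)
  }))
  out[is.finite(out$y), , drop = FALSE]
}

## Latin-hypercube starting points within box bounds, seed-controlled
lhs_starts <- function(n_starts, lower, upper, seed) {
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(lower))
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

## generic bounded multi-start Levenberg-Marquardt least squares on a
## residual function; returns the best converged fit or NULL
multistart_nls <- function(resid_fun, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lower), upper),
                         lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  best
}

#' Step I: fit the OD-weighted Gaussian basis to baseline subgroup curves
#'
#' Fits one shared parameter set (A, sigma, B, s) jointly, by nonlinear
#' least squares, to the three baseline population orientation tuning
#' curves of the grating-eye-preferring, binocular and masker-eye-preferring
#' subgroups, whose empirical mean eye weights are \code{w_groups}.
#'
#' @param baseline_curves list of three \code{population_curve} data frames.
#' @param w_groups numeric(3), subgroup mean eye weights in (0, 1).
#' @param n_starts Latin-hypercube multi-start count.
#' @param seed seed for the start design.
#' @param bounds list with \code{lower}/\code{upper} for (A, sigma, B, s).
#' @return list with \code{params} (a \code{gain_params} carrying the Step-I
#'   fields), \code{r_squared}, \code{converged}.
#' @export
step1_fit <- function(baseline_curves, w_groups, n_starts = 20, seed = 1,
                      bounds = list(lower = c(A = 1e-6, sigma = 5, B = -0.5, s = -5),
                                    upper = c(A = 10, sigma = 120, B = 1, s = 5))) {
  dat <- stack_curves(baseline_curves, w_groups)
  resid_fun <- function(p) {
    pr <- list(A = p[1], sigma = p[2], B = p[3], s = p[4])
    eq1_forward(dat$theta, dat$w, pr) - dat$y
  }
  starts <- lhs_starts(n_starts, bounds$lower, bounds$upper, seed)
  ## anchor one start at a moment-based guess
  starts[1, ] <- c(max(dat$y) - min(dat$y), 40, max(min(dat$y), 1e-3), -1)
  best <- multistart_nls(resid_fun, starts, bounds$lower, bounds$upper)
  if (is.null(best))
    return(list(params = NULL, r_squared = NA_real_, converged = FALSE))
  p <- unname(best$fit$par)
  params <- gain_params(A = p[1], sigma = p[2], B = p[3], s = p[4])
  pred <- eq1_forward(dat$theta, dat$w, params)
  list(params = params, r_squared = pooled_r2(dat$y, pred), converged = TRUE)
}

#' Step II: fit interocular suppression and summation to CFS subgroup curves
#'
#' With the Step-I parameters (A, sigma, B, s) frozen, fits (t, a_n, k,
#' b_n, m) jointly across the three CFS subgroup curves. \code{N_groups}
#' are the empirical subgroup-mean masker-only responses. The pair
#' (a_n, k) and (b_n, m) act on the curves only through the scalars
#' a_n * N^k and b_n * N^m, so the raw parameters are identifiable only up
#' to that degeneracy; the fitted curves are the contract.
#'
#' @param cfs_curves list of three \code{population_curve} data frames.
#' @param step1_params \code{gain_params} from \code{\link{step1_fit}}.
#' @param N_groups numeric(3), subgroup masker responses (dF/F0).
#' @param w_groups numeric(3), subgroup mean eye weights.
#' @param n_starts,seed multi-start control.
#' @param bounds list with \code{lower}/\code{upper} for (t, a_n, k, b_n, m).
#' @return list with \code{params} (full \code{gain_params}),
#'   \code{r_squared}, \code{converged}.
#' @export
step2_fit <- function(cfs_curves, step1_params, N_groups, w_groups,
                      n_starts = 20, seed = 1,
                      bounds = list(lower = c(t = 0, a_n = 1e-6, k = 0, b_n = 1e-6, m = 0),
                                    upper = c(t = 5, a_n = 1e3, k = 5, b_n = 1e3, m = 5))) {
  dat <- stack_curves(cfs_curves, w_groups, N_groups)
  resid_fun <- function(p) {
    pr <- list(A = step1_params$A, sigma = step1_params$sigma,
               B = step1_params$B, s = step1_params$s,
               t = p[1], a_n = p[2], k = p[3], b_n = p[4], m = p[5])
    eq23_forward(dat$theta, dat$w, pr, N = dat$N) - dat$y
  }
  starts <- lhs_starts(n_starts, bounds$lower, bounds$upper, seed)
  starts[, 2] <- exp(log(1e-2) + (log(50) - log(1e-2)) *
                       (starts[, 2] - bounds$lower[2]) /
                       (bounds$upper[2] - bounds$lower[2]))
  starts[, 4] <- exp(log(1e-3) + (log(10) - log(1e-3)) *
                       (starts[, 4] - bounds$lower[4]) /
                       (bounds$upper[4] - bounds$lower[4]))
  starts[1, ] <- c(0.5, 5, 1, 0.1, 1)
  best <- multistart_nls(resid_fun, starts, bounds$lower, bounds$upper)
  if (is.null(best))
    return(list(params = NULL, r_squared = NA_real_, converged = FALSE))
  p <- unname(best$fit$par)
  params <- gain_params(A = step1_params$A, sigma = step1_params$sigma,
                        B = step1_params$B, s = step1_params$s,
                        t = p[1], a_n = p[2], k = p[3], b_n = p[4], m = p[5],
                        N = N_groups)
  pred <- unlist(lapply(split(dat, dat$group), function(d)
    eq23_forward(d$theta, d$w, params, N = d$N)))
  obs <- unlist(lapply(split(dat, dat$group), function(d) d$y))
  list(params = params, r_squared = pooled_r2(obs, pred), converged = TRUE)
}
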