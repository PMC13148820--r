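#' Design matrix for orientation decoding
#'
#' One experimental arm (baseline = monocular, or CFS; one grating eye)
#' yields 2 SFs x 12 orientations x trials samples, each the
#' direction-averaged trial response of every neuron (neurons are the
#' features; both spatial frequencies enter as samples, so labels are the
#' 12 orientations). With 14/12/10 trials per condition this gives
#' 336/288/240 samples.
#'
#' @param responses a \code{response_tensor}.
#' @param group "monocular" or "cfs".
#' @param eye grating eye, "contra" or "ipsi".
#' @return list(X = samples x neurons matrix, y = factor of orientations,
#'   sf = numeric per sample).
#' @export
build_design <- function(responses, group = "monocular",
                         eye = c("contra", "ipsi")) {
  eye <- match.arg(eye)
  stopifnot(group %in% c("monocular", "cfs"))
  arm <- dir_avg_trials(responses, group, eye)
  n <- dim(arm$values)[1]; K <- dim(arm$values)[2]; T <- dim(arm$values)[3]
  X <- matrix(NA_real_, K * T, n)
  y <- numeric(K * T); sf <- numeric(K * T)
  r <- 0
  for (k in seq_len(K)) for (tt in seq_len(T)) {
    r <- r + 1
    X[r, ] <- arm$values[, k, tt]
    y[r] <- arm$meta$orientation[k]
    sf[r] <- arm$meta$sf[k]
  }
  list(X = X, y = factor(y), sf = sf)
}

## stratified fold assignment, seed-controlled
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < folds)
      stop("stratification error: class ", cl, " has fewer samples (",
           length(idx), ") than folds (", folds, ")")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated linear SVM orientation classification
#'
#' Stratified k-fold cross-validation of a one-vs-one linear-kernel SVM
#' (66 pairwise classifiers for 12 classes, majority vote; C = 1).
#' Features are standardized to mean 0 / SD 1 using the training fold only.
#'
#' @param X samples x features matrix.
#' @param y class labels (factor).
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @param cost SVM regularization parameter C.
#' @return list (class \code{decode_result}): \code{fold_accuracies},
#'   \code{mean_accuracy}, \code{ci95} (normal approximation across folds),
#'   \code{n_samples}, \code{n_features}, \code{chance}.
#' @export
svm_crossval <- function(X, y, folds = 10, seed = 1, cost = 1) {
  y <- droplevels(as.factor(y))
  fold <- stratified_folds(y, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    acc[f] <- mean(predict(fit, Xte) == y[te])
  }
  se <- sd(acc) / sqrt(folds)
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 ci95 = mean(acc) + c(-1, 1) * 1.96 * se,
                 n_samples = nrow(X), n_features = ncol(X),
                 chance = 1 / nlevels(y)),
            class = "decode_result")
}

#' Permutation-null decoding accuracy
#'
#' Re-runs the cross-validated decoder with labels permuted uniformly at
#' random; under the null the pooled correct count is Binomial(n, 1/k).
#'
#' @param X,y as in \code{\link{svm_crossval}}.
#' @param n_perm number of permutations.
#' @param folds,seed,cost passed through.
#' @return list(accuracies, mean_accuracy, band = exact multinomial 95%
#'   band for a single-run accuracy around 1/k).
#' @export
permutation_null_accuracy <- function(X, y, n_perm = 5, folds = 10,
                                      seed = 1, cost = 1) {
  y <- droplevels(as.factor(y))
  accs <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(seed + 7919L * p)
    yp <- sample(y)
    accs[p] <- svm_crossval(X, yp, folds = folds, seed = seed + p,
                            cost = cost)$mean_accuracy
  }
  n <- length(y); k <- nlevels(y)
  band <- qbinom(c(0.025, 0.975), n, 1 / k) / n
  list(accuracies = accs, mean_accuracy = mean(accs), band = band)
}
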