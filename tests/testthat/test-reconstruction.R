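test_that("grating targets are binary bars inside a gray circular aperture", {
  img <- render_grating(45, 3)
  expect_equal(dim(img), c(70, 70))
  expect_true(all(img %in% c(0, 0.5, 1)))
  # corners outside the aperture are mean gray
  expect_equal(img[1, 1], 0.5)
  expect_equal(img[70, 70], 0.5)
  # orientation changes the image, as does SF
  expect_false(identical(render_grating(0, 3), render_grating(90, 3)))
  expect_false(identical(render_grating(0, 3), render_grating(0, 6)))
})

test_that("augmentation quadruples the set and normalizes to [0, 1]", {
  set.seed(6)
  X <- matrix(rnorm(288 * 7, mean = 2), 288, 7)
  cond <- data.frame(orientation = rep(seq(0, 165, 15), 24),
                     sf = rep(c(3, 6), each = 144))
  aug <- augment_dataset(X, cond, factor = 4, val_frac = 0.06, seed = 1)
  expect_equal(nrow(aug$X), 1152)
  expect_equal(length(aug$val_idx), 69)       # floor(0.06 * 1152)
  expect_equal(length(aug$train_idx), 1152 - 69)
  expect_equal(unname(apply(aug$X, 2, min)), rep(0, 7))
  expect_equal(unname(apply(aug$X, 2, max)), rep(1, 7))

  # zero-SD data: augmented draws equal the condition means exactly
  X0 <- matrix(rep(cond$orientation + 10 * cond$sf, 3), 288, 3)
  aug0 <- augment_dataset(X0, cond, seed = 2)
  key <- interaction(aug0$cond$orientation, aug0$cond$sf)
  spread <- tapply(aug0$X[, 1], key, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("the compiled forward pass matches the reference implementation", {
  set.seed(12)
  n <- 9
  m <- recon_model(n, out_dim = 16, seed = 4)
  X <- matrix(runif(5 * n), 5, n)
  Y <- recon_predict(m, X)
  for (i in 1:5) {
    rf <- recon_forward(m, X[i, ])
    expect_equal(Y[i, ], rf$output, tolerance = 1e-12)
    expect_equal(unname(rowSums(rf$attention)), rep(1, n),
                 tolerance = 1e-12)
  }
  # zero query/key projections give uniform attention = column means of V
  m0 <- m; m0$WQ[] <- 0; m0$WK[] <- 0
  rf0 <- recon_forward(m0, X[1, ])
  expect_equal(rf0$attention, matrix(1 / n, n, n))
  V <- (m0$Wemb * X[1, ]) %*% m0$WV
  R2 <- rf0$attention %*% V
  expect_equal(R2, matrix(colMeans(V), n, 2, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("one optimizer step follows the RMSprop update rule exactly", {
  set.seed(5)
  n <- 5; P <- 9; S <- 4
  m <- recon_model(n, out_dim = P, seed = 7)
  X <- matrix(runif(S * n), S); Tg <- matrix(runif(S * P), S)
  lr <- 1e-4; rho <- 0.85
  tr <- train_recon(m, X, Tg, X[0, , drop = FALSE], Tg[0, , drop = FALSE],
                    epochs = 1, lr = lr, rho = rho)
  lossfun <- function(mm) mean((recon_predict(mm, X) - Tg)^2)
  h <- 1e-6
  for (nm in c("Wemb", "WQ", "Wunemb", "Wff", "bff")) {
    g_fd <- m[[nm]] * 0
    for (i in seq_along(g_fd)) {
      mp <- m; mp[[nm]][i] <- mp[[nm]][i] + h
      mn <- m; mn[[nm]][i] <- mn[[nm]][i] - h
      g_fd[i] <- (lossfun(mp) - lossfun(mn)) / (2 * h)
    }
    # after one step the accumulator is (1 - rho) g^2
    expected <- m[[nm]] - lr * g_fd / (sqrt((1 - rho) * g_fd^2) + 1e-8)
    expect_equal(tr$model[[nm]], expected, tolerance = 1e-4)
  }
})

test_that("training is deterministic, inert at lr = 0, and can memorize", {
  set.seed(13)
  n <- 8
  m <- recon_model(n, out_dim = 25, seed = 2)
  X <- matrix(runif(6 * n), 6); Tg <- matrix(runif(6 * 25), 6)
  t1 <- train_recon(m, X, Tg, X, Tg, epochs = 30, lr = 1e-3)
  t2 <- train_recon(m, X, Tg, X, Tg, epochs = 30, lr = 1e-3)
  expect_identical(t1$train_loss, t2$train_loss)
  t0 <- train_recon(m, X, Tg, X, Tg, epochs = 5, lr = 0)
  expect_equal(diff(range(t0$train_loss)), 0)
  tm <- train_recon(m, X[1, , drop = FALSE], Tg[1, , drop = FALSE],
                    X[1, , drop = FALSE], Tg[1, , drop = FALSE],
                    epochs = 6000, lr = 5e-3)
  expect_lt(tail(tm$train_loss, 1), 1e-4)
})

test_that("the sigmoid stop point obeys its closed form", {
  A <- 1; C <- 0.8; k <- 0.01; b <- 1000
  burn <- 100
  t <- 1:3000
  losses <- c(rep(A, burn), A - C / (1 + exp(k * (b - t))))
  fit <- fit_stop_point(losses, burn_in = burn)
  expect_equal(fit$stop_rel, b + log(3) / k, tolerance = 1e-9)
  expect_equal(fit$stop_rel, fit$b + log(3) / fit$k, tolerance = 1e-12)
  # fitted loss at the stop point is A - 0.75 C
  at_stop <- fit$A - fit$C / (1 + exp(fit$k * (fit$b - fit$stop_rel)))
  expect_equal(at_stop, fit$A - 0.75 * fit$C, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # noisy curves: the stop estimate stays within a few epochs
  set.seed(9)
  err <- replicate(100, {
    noisy <- losses + c(rep(0, burn),
                        rnorm(3000, sd = 0.01 * C))
    f <- fit_stop_point(noisy, burn_in = burn)
    abs(f$stop_rel - (b + log(3) / k))
  })
  expect_lt(median(err), 5)

  # an increasing curve has no defined stop point
  expect_error(fit_stop_point(rev(losses), burn_in = burn), "stop-point")
})

test_that("SSIM reproduces its closed-form values and symmetry", {
  x <- render_grating(30, 3)
  expect_equal(ssim(x, x), 1)
  # constant images: sigma terms cancel, luminance term remains
  expect_equal(ssim(matrix(0.3, 5, 5), matrix(0.7, 5, 5), c1 = 1e-4),
               (2 * 0.21 + 1e-4) / (0.09 + 0.49 + 1e-4), tolerance = 1e-12)
  # anti-correlated zero-mean images approach -1
  set.seed(4)
  z <- matrix(rnorm(100), 10, 10); z <- z - mean(z)
  expect_lt(ssim(z, -z), -0.99)
  y <- render_grating(60, 6)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-14)
  expect_true(abs(ssim(x, y)) <= 1)
})
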