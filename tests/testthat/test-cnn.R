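test_that("patch grid counts match the position formula and brute force", {
  expect_length(patch_positions(512, 32, 14), 35)   # 1225 patches per slice
  expect_length(patch_positions(512, 32, 20), 25)   # 625 patches per slice
  expect_length(patch_positions(64, 32, 32), 2)     # 4 non-overlapping
  brute <- function(n, patch, stride) {
    count <- 0; i <- 1
    while (i + patch - 1 <= n) { count <- count + 1; i <- i + stride }
    count
  }
  withr::with_seed(13, {
    for (k in 1:20) {
      n <- sample(40:600, 1); stride <- sample(1:40, 1)
      expect_length(patch_positions(n, 32, stride), brute(n, 32, stride))
    }
  })
  expect_error(patch_positions(20, 32, 4), "smaller")
})

test_that("extracted patches are co-located crops with stored normalization", {
  mk <- function(val) ct_image(matrix(val, 64, 64) +
                                 outer(1:64, 1:64), 2, units = "HU", kvp = 120)
  p <- extract_patches(list(mk(0)), list(mk(100)), list(mk(200)), stride = 32)
  expect_equal(dim(p$input), c(32, 32, 1, 4))
  expect_equal(dim(p$target), c(32, 32, 2, 4))
  # same spatial window: target minus input is the constant HU offset
  expect_equal(p$target[, , 1, 2] - p$input[, , 1, 2],
               matrix(100 / 1024, 32, 32), tolerance = 1e-12)
  expect_equal(p$target[, , 2, 3] - p$input[, , 1, 3],
               matrix(200 / 1024, 32, 32), tolerance = 1e-12)
  expect_error(extract_patches(list(mk(0)), list(mk(0)),
                               list(ct_image(matrix(0, 32, 32), 2,
                                             units = "HU"))),
               "co-registered")
})

test_that("network construction obeys the 32->18 contract", {
  expect_error(net_config(kernels = c(7, 7, 5)), "kernel")
  cfg <- net_config(channels = c(6, 4))
  net <- build_network(cfg, seed = 3)
  # all biases exactly zero at initialization
  expect_true(all(net$params$b1 == 0) && all(net$params$b2 == 0) &&
                all(net$params$b3 == 0))
  # Xavier scale bound: |w| <= sqrt(3 / fan_in)
  expect_lte(max(abs(net$params$W1)), sqrt(3 / 49))
  # same seed gives identical first-layer weights
  net2 <- build_network(cfg, seed = 3)
  expect_identical(net$params$W1, net2$params$W1)
  expect_false(identical(net$params$W1, build_network(cfg, seed = 4)$params$W1))
  # forward pass spatial contract: 32x32 -> 18x18, two output channels
  X <- array(stats::runif(32 * 32 * 3), c(32, 32, 1, 3))
  y <- pseudodect:::net_forward(net, X)$y
  expect_equal(dim(y), c(18, 18, 2, 3))
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- net_config(channels = c(2, 2))
  net <- build_network(cfg, seed = 5)
  withr::with_seed(6, {
    X <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
    T <- array(stats::runif(32 * 32 * 2 * 2), c(32, 32, 2, 2))
  })
  lg <- pseudodect:::net_loss_grad(net, X, T)
  loss_at <- function(nm, idx, eps) {
    n2 <- net
    n2$params[[nm]][idx] <- n2$params[[nm]][idx] + eps
    pseudodect:::net_loss_grad(n2, X, T)$loss
  }
  withr::with_seed(7, {
    for (nm in c("W1", "W2", "W3", "D1", "b2", "d2")) {
      idx <- sample(length(net$params[[nm]]), 1)
      fd <- (loss_at(nm, idx, 1e-6) - loss_at(nm, idx, -1e-6)) / 2e-6
      expect_equal(lg$grads[[nm]][idx], fd, tolerance = 1e-4, label = nm)
    }
  })
})

test_that("zero auxiliary weights reduce to plain final-stage training", {
  cfg0 <- net_config(channels = c(3, 3), dsn_weights = c(0, 0, 1))
  net <- build_network(cfg0, seed = 8)
  withr::with_seed(9, {
    X <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
    T <- array(stats::runif(32 * 32 * 2 * 2), c(32, 32, 2, 2))
  })
  lg <- pseudodect:::net_loss_grad(net, X, T)
  # the DSN heads receive no gradient; backbone gradients equal those of a
  # pure final-stage objective
  expect_true(all(lg$grads$D1 == 0) && all(lg$grads$D2 == 0))
  expect_equal(lg$loss, lg$losses[["final"]], tolerance = 1e-12)
})

test_that("identity task converges and training is bit-reproducible", {
  cfg <- net_config(channels = c(4, 4), dsn_weights = c(0, 0, 1),
                    activation = "relu")
  net <- build_network(cfg, seed = 1)
  ps <- identity_patch_set(n_patches = 120)
  iters <- 1500
  tr <- train_network(net, ps, iters = iters, batch = 32, seed = 2,
                      log_every = 100)
  expect_lte(iters, 5000)
  expect_lt(tr$history$final[iters], 1e-4)
  # windowed median of the loss is non-increasing over training
  med <- vapply(split(tr$history$loss, rep(1:10, each = iters / 10)),
                stats::median, 0)
  expect_true(all(diff(med) <= 1e-6))
  tr2 <- train_network(build_network(cfg, seed = 1), ps, iters = 50,
                       batch = 32, seed = 2)
  expect_identical(tr$history$loss[1:50], tr2$history$loss)
})

test_that("training aborts on divergence with a message", {
  cfg <- net_config(channels = c(3, 3))
  net <- build_network(cfg, seed = 1)
  ps <- identity_patch_set(n_patches = 40)
  expect_error(train_network(net, ps, iters = 200, lr = 500, batch = 16,
                             seed = 1),
               "diverged")
})

test_that("full-image prediction tiles, averages and handles borders", {
  cfg <- net_config(channels = c(3, 3))
  net <- build_network(cfg, seed = 2)
  img <- ct_image(matrix(100, 64, 64), 2, units = "HU", kvp = 120)
  out <- predict_full(net, img, stride = 6)
  # constant input through a convolutional network gives a constant output
  expect_equal(dim(out$pseudo_80), c(64, 64))
  expect_lt(diff(range(unclass(out$pseudo_80))), 1e-6)
  expect_equal(attr(out$pseudo_80, "kvp"), 80)
  expect_equal(attr(out$pseudo_140, "kvp"), 140)
  expect_equal(attr(out$pseudo_80, "provenance"), "pseudo-DECT")
  expect_error(predict_full(net, ct_image(matrix(0, 20, 20), 2, units = "HU")),
               "at least")
  # non-overlapping tiling reproduces per-patch outputs away from overlaps
  img2 <- ct_image(matrix(stats::rnorm(64 * 64, 0, 200), 64, 64), 2,
                   units = "HU", kvp = 120)
  o18 <- predict_full(net, img2, stride = 18)
  v <- (unclass(img2) + net$norm$offset) / net$norm$scale
  pad <- 7
  ridx <- c((pad + 1):2, 1:64, 63:(64 - pad))
  vp <- v[ridx, ridx]
  X <- array(vp[1:32, 1:32], c(32, 32, 1, 1))
  y <- pseudodect:::net_forward(net, X)$y[, , 1, 1]
  if (net$config$residual) y <- y + vp[8:25, 8:25]
  tile <- unclass(o18$pseudo_80)[1:18, 1:18]
  expect_equal(tile, y * net$norm$scale - net$norm$offset, tolerance = 1e-8)
})
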