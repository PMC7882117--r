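## Patch-based convolutional network for energy mapping: 120-kVp patches in,
## pseudo 80- and 140-kVp patches out. Three valid (no-padding) convolutional
## stages with optional dense connections and deeply supervised auxiliary
## heads, trained by SGD with momentum on an MSE loss. Implemented with
## im2col + BLAS matrix products; arrays are (h, w, channels, batch).

#' Network configuration
#'
#' Kernel sizes must satisfy `sum(kernels - 1) == 14` so a 32x32 input yields
#' an 18x18 output through valid convolutions (the 1x1 deep-supervision heads
#' add no spatial reduction).
#'
#' @param kernels integer length 3: kernel size per stage (default 7, 5, 5).
#' @param channels integer length 2: feature channels of stages 1 and 2; the
#'   third stage maps directly to the output channels.
#' @param dense use dense connections (center-cropped earlier features are
#'   concatenated to later stage inputs).
#' @param activation hidden-stage nonlinearity: `"softplus"` (default;
#'   smooth, so the network has usable curvature at initialization and fits
#'   intensity-dependent gain quickly under small iteration budgets) or
#'   `"relu"`.
#' @param residual predict the difference from the 120-kVp input rather than
#'   the raw target (residual learning): the identity component of the
#'   energy mapping is wired in, and the network only learns the
#'   energy-dependent correction, which converges far faster under
#'   scaled-down iteration budgets.
#' @param dsn_weights length 3, non-negative: loss weights of the two
#'   auxiliary heads and the final output; normalized to sum to 1.
#' @param out_channels number of output channels (2: pseudo 80 and 140 kVp).
#' @param patch,target input and output patch sizes.
#' @return A `net_config` object.
#' @export
net_config <- function(kernels = c(7, 5, 5), channels = c(64, 32),
                       dense = TRUE, residual = TRUE,
                       activation = c("softplus", "relu"),
                       dsn_weights = c(0.3, 0.3, 1),
                       out_channels = 2, patch = 32, target = 18) {
  stopifnot(length(kernels) == 3, length(channels) == 2,
            length(dsn_weights) == 3, all(dsn_weights >= 0),
            sum(dsn_weights) > 0)
  if (sum(kernels - 1) != patch - target) {
    stop("kernel sizes must satisfy sum(kernels - 1) == ", patch - target,
         " so that ", patch, " -> ", target)
  }
  structure(list(kernels = as.integer(kernels),
                 channels = as.integer(channels),
                 dense = isTRUE(dense), residual = isTRUE(residual),
                 activation = match.arg(activation),
                 dsn_weights = dsn_weights / sum(dsn_weights),
                 out_channels = as.integer(out_channels),
                 patch = as.integer(patch), target = as.integer(target)),
            class = "net_config")
}

## ---- array helpers ---------------------------------------------------------

## center crop of an (h, w, c, n) array to size x size
crop_center <- function(x, size) {
  d <- dim(x)
  o <- (d[1] - size) %/% 2
  x[o + seq_len(size), o + seq_len(size), , , drop = FALSE]
}

concat_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3], 0L)),
                    d[4]))
  at <- 0
  for (p in parts) {
    out[, , at + seq_len(dim(p)[3]), ] <- p
    at <- at + dim(p)[3]
  }
  out
}

## im2col / col2im and feature-layout reshapes are implemented in C++
## (src/im2col.cpp); the matrix products below go through BLAS.

conv_forward <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]
  oh <- d[1] - k + 1; ow <- d[2] - k + 1; cout <- dim(W)[4]
  M <- cpp_im2col(x, k)
  Y <- M %*% matrix(W, ncol = cout)
  if (any(b != 0)) Y <- sweep(Y, 2, b, "+")
  list(out = cpp_mat_to_feat(Y, oh, ow, cout, d[4]), cols = M)
}

conv_backward <- function(dY, cache_cols, W, xdim) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  dYm <- cpp_feat_to_mat(dY)
  dW <- crossprod(cache_cols, dYm)
  dim(dW) <- dim(W)
  db <- colSums(dYm)
  dM <- dYm %*% t(matrix(W, ncol = cout))
  dx <- cpp_col2im(dM, k, xdim[1], xdim[2], cin, xdim[4])
  list(dW = dW, db = db, dx = dx)
}

xavier_init <- function(k, cin, cout) {
  a <- sqrt(3 / (k * k * cin))
  array(stats::runif(k * k * cin * cout, -a, a), c(k, k, cin, cout))
}

## ---- network ---------------------------------------------------------------

#' Build the energy-mapping network
#'
#' Xavier-uniform weight initialization (scale `sqrt(3/fan_in)`, the Caffe
#' convention), all biases zero, deterministic given the seed. The forward
#' pass maps a `1 x patch x patch` input to `out_channels x target x target`.
#'
#' @param config a [net_config()].
#' @param seed RNG seed for the initialization.
#' @return A `pseudo_dect_net` object (parameters + config + intensity
#'   normalization).
#' @export
build_network <- function(config = net_config(), seed = 1) {
  k <- config$kernels; ch <- config$channels; oc <- config$out_channels
  cin2 <- ch[1] + if (config$dense) 1 else 0
  cin3 <- ch[2] + if (config$dense) ch[1] + 1 else 0
  params <- withr::with_seed(seed, list(
    W1 = xavier_init(k[1], 1, ch[1]), b1 = numeric(ch[1]),
    W2 = xavier_init(k[2], cin2, ch[2]), b2 = numeric(ch[2]),
    W3 = xavier_init(k[3], cin3, oc), b3 = numeric(oc),
    D1 = xavier_init(1, ch[1], oc), d1 = numeric(oc),
    D2 = xavier_init(1, ch[2], oc), d2 = numeric(oc)))
  structure(list(params = params, config = config,
                 norm = list(offset = 1024, scale = 1024)),
            class = "pseudo_dect_net")
}

#' @export
print.pseudo_dect_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pseudo_dect_net> stages %s, channels %s -> %d out, dense %s\n",
              paste(cfg$kernels, collapse = "/"),
              paste(cfg$channels, collapse = "/"), cfg$out_channels,
              cfg$dense))
  invisible(x)
}

## forward pass; X is (patch, patch, 1, n) normalized. Returns activations
## and caches for the backward pass.
net_forward <- function(net, X) {
  p <- net$params; cfg <- net$config
  act <- cfg$activation %||% "relu"
  c1 <- conv_forward(X, p$W1, p$b1)
  a1 <- act_forward(c1$out, act)
  s1 <- dim(a1)[1]
  in2 <- if (cfg$dense) concat_channels(a1, crop_center(X, s1)) else a1
  c2 <- conv_forward(in2, p$W2, p$b2)
  a2 <- act_forward(c2$out, act)
  s2 <- dim(a2)[1]
  in3 <- if (cfg$dense) {
    concat_channels(a2, crop_center(a1, s2), crop_center(X, s2))
  } else a2
  c3 <- conv_forward(in3, p$W3, p$b3)
  h1 <- conv_forward(a1, p$D1, p$d1)
  h2 <- conv_forward(a2, p$D2, p$d2)
  list(y = c3$out, y1 = h1$out, y2 = h2$out,
       z1 = c1$out, z2 = c2$out, a1 = a1, a2 = a2,
       X = X, in2 = in2, in3 = in3,
       cols1 = c1$cols, cols2 = c2$cols, cols3 = c3$cols,
       colsD1 = h1$cols, colsD2 = h2$cols)
}

mse <- function(y, t) mean((y - t)^2)

act_forward <- function(z, kind) {
  if (kind == "relu") return(pmax(z, 0))
  pmax(z, 0) + log1p(exp(-abs(z)))          # stable softplus
}

act_grad <- function(z, kind) {
  if (kind == "relu") return(z > 0)
  1 / (1 + exp(-z))                         # sigmoid
}

## total loss and parameter gradients for one batch. T is the full
## (patch, patch, out_channels, n) normalized target window; each head is
## compared against its center crop.
net_loss_grad <- function(net, X, T) {
  p <- net$params; cfg <- net$config; w <- cfg$dsn_weights
  f <- net_forward(net, X)
  if (cfg$residual) {
    ## targets become deviations from the (center-cropped) input
    T <- T - X[, , c(1, 1), , drop = FALSE]
  }
  t3 <- crop_center(T, dim(f$y)[1])
  t1 <- crop_center(T, dim(f$y1)[1])
  t2 <- crop_center(T, dim(f$y2)[1])
  losses <- c(stage1 = mse(f$y1, t1), stage2 = mse(f$y2, t2),
              final = mse(f$y, t3))
  loss <- sum(w * losses)

  dy <- 2 * w[3] * (f$y - t3) / length(f$y)
  dy1 <- 2 * w[1] * (f$y1 - t1) / length(f$y1)
  dy2 <- 2 * w[2] * (f$y2 - t2) / length(f$y2)

  g3 <- conv_backward(dy, f$cols3, p$W3, dim(f$in3))
  gD1 <- conv_backward(dy1, f$colsD1, p$D1, dim(f$a1))
  gD2 <- conv_backward(dy2, f$colsD2, p$D2, dim(f$a2))

  ch1 <- cfg$channels[1]; ch2 <- cfg$channels[2]
  da2 <- g3$dx[, , seq_len(ch2), , drop = FALSE] + gD2$dx
  da1 <- gD1$dx
  if (cfg$dense) {
    ## gradient flowing into the cropped a1 copy concatenated at stage 3
    s2 <- dim(f$a2)[1]
    o <- (dim(f$a1)[1] - s2) %/% 2
    da1[o + seq_len(s2), o + seq_len(s2), , ] <-
      da1[o + seq_len(s2), o + seq_len(s2), , , drop = FALSE] +
      g3$dx[, , ch2 + seq_len(ch1), , drop = FALSE]
  }
  act <- cfg$activation %||% "relu"
  dz2 <- da2 * act_grad(f$z2, act)
  g2 <- conv_backward(dz2, f$cols2, p$W2, dim(f$in2))
  da1 <- da1 + g2$dx[, , seq_len(ch1), , drop = FALSE]
  dz1 <- da1 * act_grad(f$z1, act)
  g1 <- conv_backward(dz1, f$cols1, p$W1, dim(f$X))

  list(loss = loss, losses = losses,
       grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    W3 = g3$dW, b3 = g3$db, D1 = gD1$dW, d1 = gD1$db,
                    D2 = gD2$dW, d2 = gD2$db))
}

## ---- patches ---------------------------------------------------------------

#' Patch grid positions along one axis
#' @param n axis length in pixels.
#' @param patch patch size.
#' @param stride stride between patch origins.
#' @return Integer vector of 1-based origins:
#'   `floor((n - patch)/stride) + 1` positions.
#' @export
patch_positions <- function(n, patch, stride) {
  if (n < patch) stop("image smaller than the patch size")
  seq(1L, n - patch + 1L, by = as.integer(stride))
}

#' Extract paired training patches from co-registered image stacks
#'
#' Input patches (`patch` x `patch`) come from the 120-kVp images on a
#' deterministic stride grid (optional seeded random jitter); targets are the
#' full co-located windows of the 80- and 140-kVp images, from which the
#' center crops at each supervision size are taken during training.
#' Intensities are normalized as `(HU + 1024)/1024`.
#'
#' @param imgs_120,imgs_80,imgs_140 lists of co-registered [ct_image()]s.
#' @param patch patch size (pixels).
#' @param stride stride of the extraction grid (14 for training, 20 for
#'   testing in the study protocol).
#' @param jitter maximum random offset (pixels, at most `stride/2`) added to
#'   each grid position; 0 for the deterministic grid.
#' @param seed RNG seed used when `jitter > 0`.
#' @return A `patch_set`: `input` (patch, patch, 1, P), `target`
#'   (patch, patch, 2, P), source image ids, stride and normalization.
#' @export
extract_patches <- function(imgs_120, imgs_80, imgs_140, patch = 32,
                            stride = 14, jitter = 0, seed = NULL) {
  stopifnot(length(imgs_120) == length(imgs_80),
            length(imgs_120) == length(imgs_140))
  if (jitter > stride / 2) stop("jitter must be at most stride/2")
  norm <- list(offset = 1024, scale = 1024)
  nrm <- function(img) (unclass(img) + norm$offset) / norm$scale
  one <- function(i) {
    a <- imgs_120[[i]]; b <- imgs_80[[i]]; c3 <- imgs_140[[i]]
    if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(c3))) {
      stop("image stacks are not co-registered")
    }
    px <- patch_positions(nrow(a), patch, stride)
    py <- patch_positions(ncol(a), patch, stride)
    g <- expand.grid(i = px, j = py)
    if (jitter > 0) {
      g$i <- pmin(pmax(g$i + sample(-jitter:jitter, nrow(g), TRUE), 1L),
                  nrow(a) - patch + 1L)
      g$j <- pmin(pmax(g$j + sample(-jitter:jitter, nrow(g), TRUE), 1L),
                  ncol(a) - patch + 1L)
    }
    va <- nrm(a); vb <- nrm(b); vc <- nrm(c3)
    X <- array(0, c(patch, patch, 1, nrow(g)))
    T <- array(0, c(patch, patch, 2, nrow(g)))
    for (k in seq_len(nrow(g))) {
      ii <- g$i[k] + seq_len(patch) - 1; jj <- g$j[k] + seq_len(patch) - 1
      X[, , 1, k] <- va[ii, jj]
      T[, , 1, k] <- vb[ii, jj]
      T[, , 2, k] <- vc[ii, jj]
    }
    list(X = X, T = T, id = rep(i, nrow(g)))
  }
  parts <- if (jitter > 0 && !is.null(seed)) {
    withr::with_seed(seed, lapply(seq_along(imgs_120), one))
  } else {
    lapply(seq_along(imgs_120), one)
  }
  P <- sum(vapply(parts, function(p) length(p$id), 0L))
  X <- array(0, c(patch, patch, 1, P))
  T <- array(0, c(patch, patch, 2, P))
  at <- 0
  for (p in parts) {
    np <- length(p$id)
    X[, , , at + seq_len(np)] <- p$X
    T[, , , at + seq_len(np)] <- p$T
    at <- at + np
  }
  structure(list(input = X, target = T,
                 id = unlist(lapply(parts, function(p) p$id)),
                 stride = stride, norm = norm),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d (stride %d) from %d images\n",
              dim(x$input)[4], dim(x$input)[1], dim(x$input)[2], x$stride,
              length(unique(x$id))))
  invisible(x)
}

## ---- training --------------------------------------------------------------

#' Train the network by SGD with momentum
#'
#' Mini-batches are drawn with a seeded RNG; the loss is the
#' deep-supervision-weighted sum of the per-stage MSEs. Training aborts if
#' the loss exceeds `divergence_factor` times the initial loss.
#'
#' @param net a [build_network()] result.
#' @param patches a [extract_patches()] result.
#' @param iters number of SGD iterations.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param batch mini-batch size.
#' @param seed RNG seed controlling batch sampling.
#' @param log_every record per-stage losses every this many iterations
#'   (the total loss is recorded every iteration).
#' @param checkpoint_every optionally snapshot the network parameters every
#'   this many iterations; snapshots are returned in `$checkpoints`.
#' @param divergence_factor abort threshold relative to the initial loss.
#' @return A list: the trained `net`, `history` tibble (iteration, loss and
#'   per-stage losses where logged), and the training settings.
#' @export
train_network <- function(net, patches, iters, lr = 0.01, momentum = 0.9,
                          batch = 128, seed = 1, log_every = 10,
                          checkpoint_every = NULL, divergence_factor = 1e3) {
  P <- dim(patches$input)[4]
  if (P < 1) stop("empty patch set")
  checkpoints <- list()
  vel <- lapply(net$params, function(p) p * 0)
  history <- matrix(NA_real_, iters, 4,
                    dimnames = list(NULL, c("loss", "stage1", "stage2", "final")))
  loss0 <- NULL
  net <- withr::with_seed(seed, {
    for (it in seq_len(iters)) {
      idx <- sample.int(P, min(batch, P), replace = P < batch)
      X <- patches$input[, , , idx, drop = FALSE]
      T <- patches$target[, , , idx, drop = FALSE]
      lg <- net_loss_grad(net, X, T)
      if (is.null(loss0)) loss0 <- lg$loss
      if (!is.finite(lg$loss) || lg$loss > divergence_factor * loss0) {
        stop("training diverged at iteration ", it,
             " (loss ", signif(lg$loss, 4), " vs initial ",
             signif(loss0, 4), ")")
      }
      history[it, 1] <- lg$loss
      if (it %% log_every == 0 || it == 1 || it == iters) {
        history[it, 2:4] <- lg$losses
      }
      for (nm in names(net$params)) {
        vel[[nm]] <- momentum * vel[[nm]] - lr * lg$grads[[nm]]
        net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
      }
      if (!is.null(checkpoint_every) && it %% checkpoint_every == 0) {
        checkpoints[[as.character(it)]] <- net$params
      }
    }
    net
  })
  list(net = net, checkpoints = checkpoints,
       history = tibble::tibble(iteration = seq_len(iters),
                                loss = history[, 1],
                                stage1 = history[, 2], stage2 = history[, 3],
                                final = history[, 4]),
       settings = list(iters = iters, lr = lr, momentum = momentum,
                       batch = batch, seed = seed))
}

## ---- inference -------------------------------------------------------------

reflect_pad_indices <- function(n, pad) {
  c((pad + 1):2, seq_len(n), (n - 1):(n - pad))
}

#' Predict pseudo 80/140-kVp images from a 120-kVp image
#'
#' Sliding-window inference: the image is reflect-padded by 7 pixels, 32x32
#' windows are evaluated on a stride grid (plus the final positions so the
#' whole image is covered), and the 18x18 outputs are tiled with averaging
#' over overlaps, then denormalized to HU.
#'
#' @param net a trained network (`$net` of [train_network()], or a fresh
#'   [build_network()]).
#' @param img_120 a [ct_image()] in HU (at least 32x32).
#' @param stride window stride in pixels (any value from 1 to 18).
#' @param batch windows evaluated per forward pass.
#' @return A list with `pseudo_80` and `pseudo_140` [ct_image()]s tagged with
#'   their kVp and provenance `"pseudo-DECT"`.
#' @export
predict_full <- function(net, img_120, stride = 6, batch = 256) {
  cfg <- net$config
  patch <- cfg$patch; target <- cfg$target
  pad <- (patch - target) %/% 2
  if (nrow(img_120) < patch || ncol(img_120) < patch) {
    stop("image must be at least ", patch, "x", patch)
  }
  v <- (unclass(img_120) + net$norm$offset) / net$norm$scale
  vp <- v[reflect_pad_indices(nrow(v), pad), reflect_pad_indices(ncol(v), pad)]
  npx <- nrow(vp); npy <- ncol(vp)
  pos_x <- unique(c(seq(1L, npx - patch + 1L, by = stride), npx - patch + 1L))
  pos_y <- unique(c(seq(1L, npy - patch + 1L, by = stride), npy - patch + 1L))
  g <- expand.grid(i = pos_x, j = pos_y)
  acc <- array(0, c(nrow(v), ncol(v), 2))
  cnt <- matrix(0, nrow(v), ncol(v))
  for (start in seq(1, nrow(g), by = batch)) {
    rows <- start:min(start + batch - 1, nrow(g))
    X <- array(0, c(patch, patch, 1, length(rows)))
    for (k in seq_along(rows)) {
      ii <- g$i[rows[k]] + seq_len(patch) - 1
      jj <- g$j[rows[k]] + seq_len(patch) - 1
      X[, , 1, k] <- vp[ii, jj]
    }
    Y <- net_forward(net, X)$y
    if (cfg$residual) {
      Y <- Y + crop_center(X, target)[, , c(1, 1), , drop = FALSE]
    }
    for (k in seq_along(rows)) {
      ## output tile footprint in unpadded coordinates
      oi <- g$i[rows[k]] + seq_len(target) - 1
      oj <- g$j[rows[k]] + seq_len(target) - 1
      acc[oi, oj, ] <- acc[oi, oj, , drop = FALSE] + Y[, , , k]
      cnt[oi, oj] <- cnt[oi, oj] + 1
    }
  }
  denorm <- function(ch) {
    out <- acc[, , ch] / cnt * net$norm$scale - net$norm$offset
    out
  }
  mk <- function(ch, kvp) {
    ct_image(denorm(ch), spacing = img_spacing(img_120), units = "HU",
             kvp = kvp, fov_mm = attr(img_120, "fov_mm"),
             provenance = "pseudo-DECT")
  }
  list(pseudo_80 = mk(1, 80), pseudo_140 = mk(2, 140))
}
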