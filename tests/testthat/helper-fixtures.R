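# Shared fixtures: small analytic phantoms and geometries built in code.

# uniform attenuation disk as a ct_image in mm^-1
disk_image <- function(n = 128, spacing = 2, radius = 50, mu = 0.02) {
  cx <- (seq_len(n) - (n + 1) / 2) * spacing
  v <- matrix(0, n, n)
  v[outer(cx^2, cx^2, "+") <= radius^2] <- mu
  ct_image(v, spacing = spacing, units = "mm^-1")
}

# logical mask of a circular ROI (x, y, r) on a ct_image grid
roi_disk <- function(img, roi) {
  n <- nrow(img); sp <- attr(img, "spacing")
  cx <- (seq_len(n) - (n + 1) / 2) * sp
  outer(cx - roi[1], cx - roi[2], function(a, b) a^2 + b^2) <= roi[3]^2
}

disk_mask <- function(n, spacing, radius) {
  cx <- (seq_len(n) - (n + 1) / 2) * spacing
  outer(cx^2, cx^2, "+") <= radius^2
}

# water-only cylindrical phantom spec (no inserts)
water_disk_spec <- function(radius_mm = 100) {
  phantom_spec("water-disk",
               data.frame(shape = "circle", x = 0, y = 0, rx = radius_mm,
                          ry = radius_mm, material = "water", role = "outer",
                          conc = NA_real_))
}

# printed reference coefficients of a calibrated decomposition (used as a
# known-model fixture for exact worked examples)
reference_decomp_model <- function() {
  decomp_model(
    coef_aluminum = c(0.952, 1.116, -2.353, -0.023, 0.098, -0.104,
                      -0.020, 0.042),
    coef_acrylic = c(-2.319, -2.882, 8.509, 0.088, -0.448, 0.558,
                     -0.035, 0.079),
    domain = list(L = c(0, 4), H = c(0, 3)))
}

# tiny identity-task patch set: targets equal the input windows
identity_patch_set <- function(n_patches = 200, patch = 32, seed = 7) {
  withr::with_seed(seed, {
    X <- array(stats::runif(patch * patch * n_patches, 0, 0.5),
               c(patch, patch, 1, n_patches))
  })
  T <- array(0, c(patch, patch, 2, n_patches))
  T[, , 1, ] <- X[, , 1, ]
  T[, , 2, ] <- X[, , 1, ]
  structure(list(input = X, target = T, id = rep(1, n_patches), stride = NA,
                 norm = list(offset = 1024, scale = 4096)),
            class = "patch_set")
}
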