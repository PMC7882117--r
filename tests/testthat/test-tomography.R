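test_that("Siddon traversal reproduces simple analytic rays", {
  # axis-aligned ray through 10 unit pixels
  tr <- siddon_trace(c(-100, 0.5), c(1, 0), 10, 10, 1)
  expect_length(tr$index, 10)
  expect_equal(tr$length, rep(1, 10), tolerance = 1e-12)
  # diagonal of a single 1-mm pixel
  tr <- siddon_trace(c(0, 0), c(1, 1), 1, 1, 1)
  expect_equal(sum(tr$length), sqrt(2), tolerance = 1e-12)
  # a ray that misses the grid is empty, not an error
  tr <- siddon_trace(c(0, 100), c(1, 0), 10, 10, 1)
  expect_length(tr$index, 0)
  expect_error(siddon_trace(c(0, 0), c(0, 0), 10, 10, 1), "non-zero")
})

test_that("Siddon lengths sum to the analytic box chord for random rays", {
  nx <- 37; ny <- 23; spacing <- 1.7
  xmax <- nx * spacing / 2; ymax <- ny * spacing / 2
  chord <- function(o, d) {
    # slab-intersection formula for the grid bounding box
    t0 <- -Inf; t1 <- Inf
    for (k in 1:2) {
      lim <- if (k == 1) xmax else ymax
      if (abs(d[k]) < 1e-14) {
        if (abs(o[k]) >= lim) return(0)
      } else {
        ts <- sort(c((-lim - o[k]) / d[k], (lim - o[k]) / d[k]))
        t0 <- max(t0, ts[1]); t1 <- min(t1, ts[2])
      }
    }
    max(0, t1 - t0)
  }
  withr::with_seed(11, {
    for (i in 1:1000) {
      o <- stats::runif(2, -60, 60)
      ang <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(ang), sin(ang))
      tr <- siddon_trace(o, d, nx, ny, spacing)
      expect_equal(sum(tr$length), chord(o, d), tolerance = 1e-9)
    }
  })
})

test_that("forward projection matches disk chords and is linear", {
  img <- disk_image(n = 128, spacing = 2, radius = 50, mu = 0.02)
  geom <- parallel_geometry(4, 137, 2)
  s <- forward_project(img, geom)
  offs <- (seq_len(137) - 69) * 2
  chords <- ifelse(abs(offs) < 50, 2 * 0.02 * sqrt(pmax(50^2 - offs^2, 0)), 0)
  # within one pixel-width discretization tolerance, away from the disk rim
  # where the chord derivative diverges
  central <- abs(offs) <= 40
  expect_lt(max(abs(s$values[1, central] - chords[central])), 0.02 * 2 * 2.2)

  zero <- ct_image(unclass(img) * 0, 2, units = "mm^-1")
  expect_true(all(forward_project(zero, geom)$values == 0))

  img2 <- disk_image(n = 128, spacing = 2, radius = 30, mu = 0.05)
  lin <- forward_project(ct_image(2 * unclass(img) + 3 * unclass(img2), 2,
                                  units = "mm^-1"), geom)
  expect_equal(lin$values,
               2 * forward_project(img, geom)$values +
                 3 * forward_project(img2, geom)$values,
               tolerance = 1e-10)
  expect_error(forward_project(ct_image(unclass(img)[, ], 2, units = "HU"),
                               geom),
               "mm")
})

test_that("ray backprojection is the exact adjoint of forward projection", {
  n <- 24; spacing <- 1.3
  geom <- parallel_geometry(17, 31, spacing)
  withr::with_seed(3, {
    for (rep in 1:5) {
      x <- matrix(stats::rnorm(n * n), n, n)
      y <- matrix(stats::rnorm(geom$n_views * geom$n_bins), geom$n_views)
      Ax <- forward_project(ct_image(x, spacing, units = "mm^-1"), geom)
      Aty <- backproject(sinogram(y, geom), n, n, spacing)
      expect_equal(sum(Ax$values * y), sum(x * Aty), tolerance = 1e-6)
    }
  })
})

test_that("sinogram of a centered disk is angle-invariant", {
  img <- disk_image(n = 96, spacing = 2, radius = 40, mu = 0.03)
  geom <- parallel_geometry(24, 105, 2)
  s <- forward_project(img, geom)
  offs <- (seq_len(105) - 53) * 2
  spread <- apply(s$values, 2, function(col) max(col) - min(col))
  expect_lt(max(spread[abs(offs) <= 24]), 0.03 * 2 * 2.5)
})

test_that("FBP recovers a uniform disk within 2 percent", {
  img <- disk_image(n = 128, spacing = 2, radius = 50, mu = 0.02)
  geom <- parallel_geometry(360, 137, 2)
  s <- forward_project(img, geom)
  rec <- fbp_reconstruct(s, 128, 2)
  inside <- disk_mask(128, 2, 40)
  expect_equal(mean(unclass(rec)[inside]), 0.02, tolerance = 0.02)
  # zero sinogram reconstructs to a zero image
  z <- fbp_reconstruct(sinogram(s$values * 0, geom), 128, 2)
  expect_true(all(unclass(z) == 0))
  expect_error(fbp_reconstruct(sinogram(s$values[1, , drop = FALSE],
                                        parallel_geometry(1, 137, 2)),
                               128, 2),
               "views")
})

test_that("doubling the view count reduces reconstruction error", {
  img <- disk_image(n = 96, spacing = 2, radius = 45, mu = 0.025)
  err <- vapply(c(90, 180), function(nv) {
    geom <- parallel_geometry(nv, 105, 2)
    rec <- fbp_reconstruct(forward_project(img, geom), 96, 2)
    sqrt(mean((unclass(rec) - unclass(img))[disk_mask(96, 2, 60)]^2))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("sinogram containers validate shape and round-trip through text", {
  geom <- parallel_geometry(10, 20, 1.5)
  expect_error(sinogram(matrix(0, 5, 20), geom), "shape")
  expect_error(sinogram(matrix(NA_real_, 10, 20), geom), "finite")
  s <- sinogram(matrix(stats::rnorm(200), 10, 20), geom, energy = 80)
  path <- tempfile(fileext = ".tsv")
  write_sinogram(s, path)
  s2 <- read_sinogram(path)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(s2$geometry$pitch, 1.5)
  expect_equal(s2$energy, 80)
})
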