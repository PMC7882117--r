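test_that("RMSE and PSNR follow their closed forms", {
  a <- ct_image(matrix(stats::rnorm(400), 20, 20), 1, units = "HU")
  same <- rmse_psnr(a, a)
  expect_equal(same$rmse, 0)
  expect_true(is.infinite(same$psnr))
  shifted <- ct_image(unclass(a) + 10, 1, units = "HU")
  expect_equal(rmse_psnr(a, shifted)$rmse, 10, tolerance = 1e-12)
  withr::with_seed(21, {
    b <- ct_image(unclass(a) + matrix(stats::rnorm(400, 0, 5), 20, 20), 1,
                  units = "HU")
  })
  got <- rmse_psnr(a, b, i_max = 3095)
  # independent brute-force re-implementation of the formulas
  rmse <- sqrt(sum((unclass(a) - unclass(b))^2) / 400)
  expect_equal(got$rmse, rmse, tolerance = 1e-10)
  expect_equal(got$psnr, 20 * log10(3095 / rmse), tolerance = 1e-10)
  expect_error(rmse_psnr(a, ct_image(matrix(0, 5, 5), 1, units = "HU")),
               "grids")
  expect_error(rmse_psnr(a, b, mask = matrix(FALSE, 20, 20)), "mask")
})

test_that("PSNR decreases as independent noise is added", {
  a <- ct_image(matrix(0, 30, 30), 1, units = "HU")
  psnrs <- vapply(c(1, 5, 25), function(s) {
    withr::with_seed(3, {
      b <- ct_image(matrix(stats::rnorm(900, 0, s), 30, 30), 1, units = "HU")
    })
    rmse_psnr(a, b)$psnr
  }, 0)
  expect_true(all(diff(psnrs) < 0))
})

test_that("metrics ignore pixels outside the mask", {
  a <- ct_image(matrix(0, 20, 20), 1, units = "HU")
  b <- ct_image(matrix(0, 20, 20), 1, units = "HU")
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  b2 <- unclass(b); b2[1, 1] <- 1e6
  expect_equal(rmse_psnr(a, ct_image(b2, 1, units = "HU"), mask)$rmse, 0)
})

test_that("CNR matches its definition and is scale invariant", {
  v <- matrix(0, 40, 40)
  img <- ct_image(v, 2, units = "HU")
  roi <- c(-20, -20, 6); bg <- c(20, 20, 10)
  withr::with_seed(5, {
    v[roi_disk(img, bg)] <- stats::rnorm(sum(roi_disk(img, bg)), 0, 1)
  })
  v[roi_disk(img, roi)] <- 5
  img <- ct_image(v, 2, units = "HU")
  m_bg <- mean(v[roi_disk(img, bg)]); s_bg <- stats::sd(v[roi_disk(img, bg)])
  expect_equal(cnr(img, roi, bg), (5 - m_bg) / s_bg, tolerance = 1e-12)
  img3 <- ct_image(3 * v, 2, units = "HU")
  expect_equal(cnr(img3, roi, bg), cnr(img, roi, bg), tolerance = 1e-12)
  # roi == bg means zero contrast
  expect_equal(cnr(img, c(-20, 20, 5),
                   bg), (roi_mean(img, -20, 20, 5) - m_bg) / s_bg,
               tolerance = 1e-12)
  expect_error(cnr(img, c(19, 19, 6), bg), "overlap")
  flat <- ct_image(matrix(1, 40, 40), 2, units = "HU")
  expect_error(cnr(flat, roi, bg), "zero")
})

test_that("coefficient of variation has its closed form", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  withr::with_seed(8, {
    for (k in 1:10) {
      v <- stats::runif(6, 1, 10)
      expect_equal(coefficient_of_variation(v),
                   sqrt(sum((v - mean(v))^2) / 5) / mean(v),
                   tolerance = 1e-12)
    }
  })
  expect_error(coefficient_of_variation(3), "2 values")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
})

strip_mask <- function(m) matrix(as.logical(m), nrow(m))

test_that("evaluation mask is the support/FOV intersection", {
  support <- matrix(FALSE, 50, 50)
  support[11:40, 11:40] <- TRUE
  m_big <- make_mask(support, fov_mm = 1e4, spacing = 2)
  expect_equal(strip_mask(m_big), support)   # FOV larger than the phantom
  m_small <- make_mask(support, fov_mm = 40, spacing = 2)
  expect_lt(sum(m_small), sum(support))
  # brute-force pixel test on random shapes
  withr::with_seed(9, {
    for (k in 1:5) {
      sup <- matrix(stats::runif(2500) < 0.5, 50, 50)
      fov <- stats::runif(1, 20, 120)
      m <- make_mask(sup, fov, 2)
      cx <- (seq_len(50) - 25.5) * 2
      ref <- sup & (outer(cx^2, cx^2, "+") <= (fov / 2)^2)
      expect_identical(strip_mask(m), ref)
    }
  })
  expect_error(make_mask(matrix(FALSE, 10, 10), 100, 1), "empty")
  corner <- matrix(FALSE, 50, 50); corner[1:5, 1:5] <- TRUE
  expect_error(make_mask(corner, 10, 2), "empty")
})
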