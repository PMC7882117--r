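test_that("virtual monochromatic projection synthesis is exactly linear", {
  geom <- parallel_geometry(5, 9, 1)
  a1 <- sinogram(matrix(stats::runif(45), 5, 9), geom, units = "mm")
  b1 <- sinogram(matrix(stats::runif(45), 5, 9), geom, units = "mm")
  a2 <- sinogram(2 * a1$values, geom, units = "mm")
  b2 <- sinogram(3 * b1$values, geom, units = "mm")
  z <- sinogram(matrix(0, 5, 9), geom, units = "mm")
  e <- 70
  mu_b <- attenuation_coefficient("acrylic", e)
  # x_A = 0 everywhere: projection is mu_B(E) x_B
  expect_equal(synthesize_vm_projection(z, b1, e)$values, mu_b * b1$values,
               tolerance = 1e-14)
  # additivity in both basis sinograms
  s12 <- synthesize_vm_projection(a2, b2, e)
  expect_equal(s12$values,
               2 * synthesize_vm_projection(a1, z, e)$values +
                 3 * synthesize_vm_projection(z, b1, e)$values,
               tolerance = 1e-12)
  expect_error(synthesize_vm_projection(a1, b1, 5), "range")
})

test_that("water-equivalent basis pair reproduces water attenuation", {
  # solve the 2x2 monochromatic system so aluminum+acrylic matches water at
  # two anchor energies, then check intermediate energies via the VM formula
  anchors <- c(50, 90)
  M <- rbind(attenuation_coefficient("aluminum", anchors),
             attenuation_coefficient("acrylic", anchors))
  M <- t(M)
  path <- 100  # mm of water
  tw <- solve(M, attenuation_coefficient("water", anchors) * path)
  for (e in seq(40, 100, by = 10)) {
    vm <- attenuation_coefficient("aluminum", e) * tw[1] +
      attenuation_coefficient("acrylic", e) * tw[2]
    expect_equal(vm, attenuation_coefficient("water", e) * path,
                 tolerance = 0.02 * attenuation_coefficient("water", e) * path)
  }
})

test_that("VMCT reconstruction hits water HU and tracks iodine energy trend", {
  # water disk expressed in basis thickness sinograms via the anchor solve
  geom <- parallel_geometry(180, 105, 2)
  img <- disk_image(n = 96, spacing = 2, radius = 60,
                    mu = attenuation_coefficient("water", 60))
  sino_w <- forward_project(img, geom)
  anchors <- c(50, 90)
  M <- t(rbind(attenuation_coefficient("aluminum", anchors),
               attenuation_coefficient("acrylic", anchors)))
  muw <- attenuation_coefficient("water", anchors) /
    attenuation_coefficient("water", 60)
  tw <- solve(M, muw)
  xa <- sinogram(tw[1] * sino_w$values, geom, units = "mm")
  xb <- sinogram(tw[2] * sino_w$values, geom, units = "mm")
  for (e in c(40, 80)) {
    vm <- synthesize_vm_projection(xa, xb, e)
    rec <- reconstruct_vmct(vm, 96, 2)
    ## the two-anchor basis representation of water is good to ~2%, which at
    ## 40 keV corresponds to a few tens of HU
    expect_lt(abs(mean(unclass(rec)[disk_mask(96, 2, 45)])), 35)
    expect_equal(attr(rec, "energy_kev"), e)
  }
  # zero sinogram: air everywhere
  rec0 <- reconstruct_vmct(sinogram(sino_w$values * 0, geom, energy = 60),
                           96, 2)
  expect_true(all(abs(unclass(rec0) + 1000) < 1e-6))
  expect_error(reconstruct_vmct(sinogram(sino_w$values, geom, energy = 20),
                                96, 2),
               "range")
})

test_that("iodine syringe HU in VMCT decreases from 40 to 100 keV", {
  ratio <- vapply(seq(40, 100, 20), function(e) {
    attenuation_coefficient("iodine_17.5", e) /
      attenuation_coefficient("water", e)
  }, 0)
  expect_true(all(diff(ratio) < 0))
})

test_that("image-based VMCT agrees with projection route on mono inputs", {
  e_l <- effective_energy(80); e_h <- effective_energy(140)
  spec <- build_calibration_phantom(18)
  m <- rasterize(spec, 96, 2.2)
  geom <- scan_geometry(96, 2.2)
  make_img <- function(e, kvp) {
    s <- simulate_polychromatic_sinogram(
      m, monochromatic_spectrum(round(e)), geom, noise = FALSE)
    mu <- fbp_reconstruct(s, 96, 2.2)
    mu <- ct_image(unclass(mu), 2.2, units = "mm^-1", kvp = kvp)
    mu_to_hu(mu)
  }
  img_l <- make_img(e_l, 80); img_h <- make_img(e_h, 140)
  ib <- vmct_image_based(img_l, img_h, 60)
  # projection route on the same monochromatic data
  Minv <- solve(rbind(
    c(attenuation_coefficient("aluminum", e_l),
      attenuation_coefficient("acrylic", e_l)),
    c(attenuation_coefficient("aluminum", e_h),
      attenuation_coefficient("acrylic", e_h))))
  sl <- forward_project(hu_to_mu(img_l), geom)
  sh <- forward_project(hu_to_mu(img_h), geom)
  xa <- sinogram(Minv[1, 1] * sl$values + Minv[1, 2] * sh$values, geom,
                 units = "mm")
  xb <- sinogram(Minv[2, 1] * sl$values + Minv[2, 2] * sh$values, geom,
                 units = "mm")
  pb <- reconstruct_vmct(synthesize_vm_projection(xa, xb, 60), 96, 2.2)
  ## the two routes differ by one application of FBP(forward(.)) - identity,
  ## a ~1-2% reconstruction-operator residual
  inside <- disk_mask(96, 2.2, 80)
  expect_lt(sqrt(mean((unclass(ib) - unclass(pb))[inside]^2)), 60)
  expect_error(vmct_image_based(img_l, disk_image(n = 64), 60),
               "co-registered")
})

test_that("identical water images at their own energies give a flat output", {
  v <- matrix(0, 32, 32)
  img_l <- ct_image(v, 2, units = "HU", kvp = 80)
  img_h <- ct_image(v, 2, units = "HU", kvp = 140)
  out <- vmct_image_based(img_l, img_h, 60)
  expect_lt(max(unclass(out)) - min(unclass(out)), 1e-9)
  expect_lt(abs(mean(unclass(out))), 1)
})

test_that("iodine factor calibration follows the closed-form regression", {
  conc <- c(0, 2, 4, 8, 16)
  k <- 0.02
  cal <- calibrate_iodine_factor(
    data.frame(value = k * conc, concentration = conc))
  expect_equal(cal$factor, 1 / k, tolerance = 1e-10)
  # zero-concentration prediction consistent with the origin constraint
  expect_lt(abs(cal$factor * 0), 2 * cal$se + 1e-12)
  withr::with_seed(2, {
    ok <- 0
    for (rep in 1:20) {
      v <- k * conc + stats::rnorm(5, 0, 0.002)
      cal2 <- calibrate_iodine_factor(
        data.frame(value = v, concentration = conc))
      b <- sum(v * conc) / sum(v^2)      # closed-form oracle
      expect_equal(cal2$factor, b, tolerance = 1e-12)
      if (abs(cal2$factor - 1 / k) <= 3 * cal2$se / k^2 * k) ok <- ok + 1
    }
  })
  expect_error(calibrate_iodine_factor(
    data.frame(value = c(1, 2), concentration = c(3, 3))), "distinct")
  expect_error(calibrate_iodine_factor(
    data.frame(value = c(-1, -2), concentration = c(1, 2))), "factor")
})

test_that("iodine map is the scaled FBP of the aluminum sinogram", {
  geom <- parallel_geometry(90, 73, 2)
  img <- disk_image(n = 64, spacing = 2, radius = 30, mu = 0.1)
  xa <- forward_project(img, geom)
  xa <- sinogram(xa$values, geom, units = "mm")
  cal <- calibrate_iodine_factor(
    data.frame(value = c(0.1, 0.2), concentration = c(5, 10)))
  m1 <- iodine_map(xa, cal, 64, 2)
  expect_equal(attr(m1, "units"), "mg/ml")
  # doubling the sinogram doubles every concentration (linearity)
  xa2 <- sinogram(2 * xa$values, geom, units = "mm")
  m2 <- iodine_map(xa2, cal, 64, 2)
  expect_equal(unclass(m2), 2 * unclass(m1), tolerance = 1e-10)
  # all-zero aluminum sinogram maps to zero concentration
  m0 <- iodine_map(sinogram(xa$values * 0, geom, units = "mm"), cal, 64, 2)
  expect_true(all(m0 == 0))
})
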