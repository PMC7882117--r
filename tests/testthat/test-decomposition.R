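test_that("rational model evaluates worked examples exactly", {
  m <- reference_decomp_model()
  est <- evaluate_decomposition(m, 0, 0)
  # at (L, H) = (0, 0) the rational functions reduce to their intercepts
  expect_identical(est$x_A, 0.952)
  expect_identical(est$x_B, -2.319)
  # hand-built model with a1 = 1 and unit denominators is the identity in L
  ident <- decomp_model(c(0, 1, 0, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0, 0, 0),
                        domain = list(L = c(0, 5), H = c(0, 5)))
  L <- seq(0, 5, 0.5)
  expect_equal(evaluate_decomposition(ident, L, L * 0)$x_A, L)
})

test_that("denominator guards trip with the branch named", {
  m <- decomp_model(c(0, 1, 0, 0, 0, 0, -0.1, 0), c(0, 0, 1, 0, 0, 0, 0, 0),
                    domain = list(L = c(0, 5), H = c(0, 5)))
  expect_error(evaluate_decomposition(m, 10, 0), "aluminum")
  expect_error(decomp_model(c(0, 1, 0, 0, 0, 0, -1, 0),
                            c(0, 0, 1, 0, 0, 0, 0, 0),
                            domain = list(L = c(0, 5), H = c(0, 5))),
               "denominator")
})

test_that("monochromatic calibration recovers the exact linear inversion", {
  # L, H exactly linear in thickness with a known 2x2 matrix
  mu <- rbind(c(attenuation_coefficient("aluminum", 50),
                attenuation_coefficient("acrylic", 50)),
              c(attenuation_coefficient("aluminum", 80),
                attenuation_coefficient("acrylic", 80)))
  g <- expand.grid(x_A = c(0, 6, 12, 18, 24, 30),
                   x_B = c(5, 10, 15, 20, 25, 30, 35, 40))
  s <- tibble::tibble(x_A = g$x_A, x_B = g$x_B,
                      L = mu[1, 1] * g$x_A + mu[1, 2] * g$x_B,
                      H = mu[2, 1] * g$x_A + mu[2, 2] * g$x_B)
  m <- fit_decomposition(s)
  est <- evaluate_decomposition(m, s$L, s$H)
  # closed-form 2x2 inversion is the oracle: every thickness is recovered
  truth <- solve(mu) %*% rbind(s$L, s$H)
  expect_lt(max(abs(est$x_A - truth[1, ])), 1e-6)
  expect_lt(max(abs(est$x_B - truth[2, ])), 1e-6)
})

test_that("refitting samples from a known model reproduces its predictions", {
  gen <- reference_decomp_model()
  g <- expand.grid(L = seq(0.2, 2.6, length.out = 25),
                   H = seq(0.1, 1.6, length.out = 25))
  truth <- evaluate_decomposition(gen, g$L, g$H)
  keep <- truth$x_A >= 0 & truth$x_B >= 0     # physically admissible samples
  g <- g[keep, ];
  s <- tibble::tibble(x_A = truth$x_A[keep], x_B = truth$x_B[keep],
                      L = g$L, H = g$H)
  expect_gt(nrow(s), 30)
  m <- fit_decomposition(s)
  est <- evaluate_decomposition(m, g$L, g$H)
  expect_lt(max(abs(est$x_A - s$x_A)), 1e-3)
  expect_lt(max(abs(est$x_B - s$x_B)), 1e-3)
})

test_that("duplicated samples leave the absolute-error fit unchanged", {
  w <- build_step_wedge()
  pl <- simulate_wedge_projection(w, generate_spectrum(80), seed = 4)
  ph <- simulate_wedge_projection(w, generate_spectrum(140), seed = 5)
  s <- measure_wedge_LH(pl, ph, w)
  m1 <- fit_decomposition(s)
  m2 <- fit_decomposition(rbind(s, s))
  est1 <- evaluate_decomposition(m1, s$L, s$H)
  est2 <- evaluate_decomposition(m2, s$L, s$H)
  expect_equal(est1$x_A, est2$x_A, tolerance = 1e-4)
  expect_equal(est1$x_B, est2$x_B, tolerance = 1e-4)
})

test_that("fit rejects degenerate calibration designs", {
  s <- tibble::tibble(x_A = rep(1:4, 4), x_B = rep(1:4, each = 4),
                      L = seq(0.1, 1.6, 0.1), H = 2 * seq(0.1, 1.6, 0.1))
  expect_error(fit_decomposition(s), "collinear|degenerate")
  expect_error(fit_decomposition(s[1:10, ]), "16")
  s2 <- s
  s2$x_A <- 1
  expect_error(fit_decomposition(s2), "distinct")
})

test_that("thickness estimates are monotone along each wedge axis", {
  w <- build_step_wedge()
  pl <- simulate_wedge_projection(w, generate_spectrum(80), seed = 8)
  ph <- simulate_wedge_projection(w, generate_spectrum(140), seed = 9)
  s <- measure_wedge_LH(pl, ph, w)
  m <- fit_decomposition(s)
  est <- evaluate_decomposition(m, s$L, s$H)
  for (b in unique(s$x_B)) {
    sel <- s$x_B == b
    expect_true(all(diff(est$x_A[sel][order(s$x_A[sel])]) > 0))
  }
  for (a in unique(s$x_A)) {
    sel <- s$x_A == a
    expect_true(all(diff(est$x_B[sel][order(s$x_B[sel])]) > 0))
  }
})

test_that("noise-free wedge validation errors are below 0.1 mm in-sample", {
  w <- build_step_wedge()
  pl <- simulate_wedge_projection(w, generate_spectrum(80), noise = FALSE)
  ph <- simulate_wedge_projection(w, generate_spectrum(140), noise = FALSE)
  s <- measure_wedge_LH(pl, ph, w)
  m <- fit_decomposition(s)
  val <- validate_wedge(m, pl, ph, w)
  expect_lt(max(val$aluminum$mae), 0.1)
  expect_lt(max(val$acrylic$mae), 0.1)
  # decomposition error on calibration rays is bounded by the fit report
  expect_lte(max(val$aluminum$mae), max(abs(m$fit$residuals$err_A)) + 1e-12)
  expect_lte(max(val$acrylic$mae), max(abs(m$fit$residuals$err_B)) + 1e-12)
})

test_that("sinogram decomposition is element-wise and guards geometry", {
  geom <- parallel_geometry(6, 11, 1)
  ident <- decomp_model(c(0.5, 1, 0, 0, 0, 0, 0, 0),
                        c(0.25, 0, 1, 0, 0, 0, 0, 0),
                        domain = list(L = c(0, 5), H = c(0, 5)))
  z <- sinogram(matrix(0, 6, 11), geom)
  dec <- decompose_sinograms(ident, z, z)
  # zero sinograms with an identity-like model give the constant intercepts
  expect_true(all(dec$x_A$values == 0.5))
  expect_true(all(dec$x_B$values == 0.25))
  expect_equal(dec$x_A$units, "mm")
  other <- sinogram(matrix(0, 6, 12), parallel_geometry(6, 12, 1))
  expect_error(decompose_sinograms(ident, z, other), "geometr")
})

test_that("decomposition model JSON round trip is exact", {
  m <- reference_decomp_model()
  path <- tempfile(fileext = ".json")
  write_decomp_model(m, path)
  m2 <- read_decomp_model(path)
  expect_identical(m2$coef_aluminum, m$coef_aluminum)
  expect_identical(m2$coef_acrylic, m$coef_acrylic)
  expect_equal(m2$domain, m$domain)
})
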