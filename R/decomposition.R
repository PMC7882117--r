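## Projection-domain two-material (aluminum/acrylic) decomposition:
## rational-function model, absolute-error parameterization on step-wedge
## calibration samples, sinogram decomposition and wedge validation.

#' Two-material decomposition model
#'
#' Rational functions mapping a (low, high) projection pair to equivalent
#' basis-material thicknesses:
#' `x_A = (a0 + a1 L + a2 H + a3 L^2 + a4 L H + a5 H^2) / (1 + b0 L + b1 H)`
#' and analogously `x_B` with coefficients `c`, `d`. The coefficients absorb
#' the beam spectra, which is why they are fitted per spectrum pair.
#'
#' @param coef_aluminum numeric length 8: `a0..a5, b0, b1`.
#' @param coef_acrylic numeric length 8: `c0..c5, d0, d1`.
#' @param domain list with `L` and `H` ranges over which the model was
#'   calibrated; the denominators are verified non-zero over this domain.
#' @param fit optional fit report (residual table etc.) attached as metadata.
#' @return A `decomp_model` object.
#' @export
decomp_model <- function(coef_aluminum, coef_acrylic,
                         domain = list(L = c(0, 0), H = c(0, 0)), fit = NULL) {
  stopifnot(length(coef_aluminum) == 8, length(coef_acrylic) == 8,
            all(is.finite(coef_aluminum)), all(is.finite(coef_acrylic)))
  m <- structure(list(coef_aluminum = unname(coef_aluminum),
                      coef_acrylic = unname(coef_acrylic),
                      domain = domain, fit = fit),
                 class = "decomp_model")
  gl <- seq(domain$L[1], domain$L[2], length.out = 21)
  gh <- seq(domain$H[1], domain$H[2], length.out = 21)
  g <- expand.grid(L = gl, H = gh)
  for (branch in c("aluminum", "acrylic")) {
    cf <- m[[paste0("coef_", branch)]]
    den <- 1 + cf[7] * g$L + cf[8] * g$H
    if (min(den) <= 0 && max(den) >= 0) {
      stop(branch, " branch denominator vanishes over the calibrated domain")
    }
  }
  m
}

#' @export
print.decomp_model <- function(x, ...) {
  cat("<decomp_model> aluminum/acrylic rational decomposition\n")
  cat("  a0..a5, b0, b1:", signif(x$coef_aluminum, 4), "\n")
  cat("  c0..c5, d0, d1:", signif(x$coef_acrylic, 4), "\n")
  if (!is.null(x$fit)) {
    cat(sprintf("  fit MAE: %.4g mm (aluminum), %.4g mm (acrylic), n = %d\n",
                x$fit$mae_aluminum, x$fit$mae_acrylic, nrow(x$fit$residuals)))
  }
  invisible(x)
}

rational_eval <- function(cf, L, H, branch, eps = 1e-6) {
  num <- cf[1] + cf[2] * L + cf[3] * H + cf[4] * L^2 + cf[5] * L * H +
    cf[6] * H^2
  den <- 1 + cf[7] * L + cf[8] * H
  if (any(abs(den) < eps)) {
    stop("denominator of the ", branch, " branch is within ", eps, " of zero")
  }
  num / den
}

#' Evaluate the decomposition at projection values
#'
#' With `extrapolation = "rational"` the fitted rational functions are
#' evaluated everywhere (the calibrated formula, exact at any point). With
#' `extrapolation = "linear"`, points outside the calibrated (L, H) domain
#' are continued linearly from the nearest domain point (first-order Taylor
#' expansion of the rational function there): the fitted curvature is a
#' within-domain description of residual beam hardening and has no support
#' beyond the wedge, where body-scale projections live.
#'
#' @param model a [decomp_model()].
#' @param L,H projection values (vectors or matrices of equal shape).
#' @param extrapolation `"rational"` (default) or `"linear"`.
#' @return A list with `x_A` and `x_B` thickness estimates in mm, same shape
#'   as the inputs.
#' @export
evaluate_decomposition <- function(model, L, H,
                                   extrapolation = c("rational", "linear")) {
  extrapolation <- match.arg(extrapolation)
  if (extrapolation == "rational") {
    return(list(x_A = rational_eval(model$coef_aluminum, L, H, "aluminum"),
                x_B = rational_eval(model$coef_acrylic, L, H, "acrylic")))
  }
  Lc <- pmin(pmax(L, model$domain$L[1]), model$domain$L[2])
  Hc <- pmin(pmax(H, model$domain$H[1]), model$domain$H[2])
  one <- function(cf, branch) {
    den <- 1 + cf[7] * Lc + cf[8] * Hc
    if (any(abs(den) < 1e-6)) {
      stop("denominator of the ", branch, " branch is within 1e-06 of zero")
    }
    num <- cf[1] + cf[2] * Lc + cf[3] * Hc + cf[4] * Lc^2 +
      cf[5] * Lc * Hc + cf[6] * Hc^2
    f <- num / den
    dnum_l <- cf[2] + 2 * cf[4] * Lc + cf[5] * Hc
    dnum_h <- cf[3] + cf[5] * Lc + 2 * cf[6] * Hc
    gl <- (dnum_l * den - num * cf[7]) / den^2
    gh <- (dnum_h * den - num * cf[8]) / den^2
    f + gl * (L - Lc) + gh * (H - Hc)
  }
  out <- list(x_A = one(model$coef_aluminum, "aluminum"),
              x_B = one(model$coef_acrylic, "acrylic"))
  dim(out$x_A) <- dim(L); dim(out$x_B) <- dim(L)
  out
}

## L1 fit of one rational branch via iteratively reweighted least squares on
## the linearized system x (1 + b0 L + b1 H) = poly(L, H); the weights
## 1 / (|r| (1 + D)^2) make the weighted quadratic objective the true
## absolute-error objective at the current iterate.
fit_branch <- function(x, L, H, max_iter = 500, tol = 1e-6, delta = 1e-8) {
  Z <- cbind(1, L, H, L^2, L * H, H^2, -x * L, -x * H)
  if (qr(cbind(1, L, H))$rank < 3) {
    stop("degenerate calibration design: (L, H) samples are collinear")
  }
  solve_wls <- function(w, cols = seq_len(ncol(Z))) {
    A <- Z[, cols, drop = FALSE] * sqrt(w)
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-10
    ## minimum-norm solution: terms the data cannot identify (e.g. the
    ## quadratic terms in the monochromatic limit) collapse to zero
    th <- numeric(ncol(Z))
    th[cols] <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% (x * sqrt(w))) / sv$d[keep])
    th
  }
  objective <- function(th) {
    den <- 1 + th[7] * L + th[8] * H
    if (any(abs(den) < 1e-9)) return(Inf)
    ## linearized residual Z th - x equals den * (num/den - x), so the true
    ## rational-model residual is its ratio with the denominator
    sum(abs((Z %*% th - x) / den))
  }
  ## numerator-only initialization (denominator = 1)
  theta <- solve_wls(rep(1, length(x)), cols = 1:6)
  obj <- objective(theta)
  for (it in seq_len(max_iter)) {
    den <- 1 + theta[7] * L + theta[8] * H
    r <- (Z %*% theta - x) / den
    w <- 1 / (sqrt(r^2 + delta^2) * den^2)
    cand <- solve_wls(as.numeric(w))
    ## damped update: IRLS for an L1 objective can cycle, so backtrack until
    ## the true objective does not increase
    step <- 1
    repeat {
      trial <- theta + step * (cand - theta)
      obj_try <- objective(trial)
      if (obj_try <= obj || step < 1e-12) break
      step <- step / 2
    }
    done <- abs(obj - obj_try) < tol * max(1, obj)
    theta <- trial; obj <- obj_try
    if (done) {
      return(list(coef = as.numeric(theta), objective = obj, iterations = it))
    }
  }
  stop("absolute-error fit did not converge in ", max_iter,
       " iterations (last objective ", signif(obj, 6), " mm)")
}

#' Fit the decomposition model from calibration samples
#'
#' Parameterization: the 16 rational-function coefficients are fitted by
#' minimizing the summed absolute thickness error over the calibration
#' samples, independently for the aluminum and acrylic branches (iteratively
#' reweighted least squares with a linear least-squares initialization).
#'
#' @param samples data frame with columns `x_A`, `x_B` (true thicknesses, mm)
#'   and `L`, `H` (measured projection values), e.g. from
#'   [measure_wedge_LH()]. At least 16 samples spanning at least 2 distinct
#'   values of each thickness.
#' @param max_iter,tol IRLS iteration cap and relative per-iteration
#'   objective-decrease tolerance (the iteration is declared converged when
#'   the absolute-error objective improves by less than `tol` of its value).
#' @return A [decomp_model()] with a fit report (`$fit`): residual table and
#'   per-branch mean absolute errors.
#' @export
fit_decomposition <- function(samples, max_iter = 500, tol = 1e-6) {
  stopifnot(all(c("x_A", "x_B", "L", "H") %in% names(samples)))
  if (nrow(samples) < 16) stop("need at least 16 calibration samples")
  if (length(unique(samples$x_A)) < 2 || length(unique(samples$x_B)) < 2) {
    stop("calibration must span at least 2 distinct thicknesses per material")
  }
  if (any(samples$x_A < 0) || any(samples$x_B < 0)) {
    stop("calibration thicknesses must be non-negative")
  }
  fa <- fit_branch(samples$x_A, samples$L, samples$H, max_iter, tol)
  fb <- fit_branch(samples$x_B, samples$L, samples$H, max_iter, tol)
  domain <- list(L = range(samples$L), H = range(samples$H))
  pred_a <- rational_eval(fa$coef, samples$L, samples$H, "aluminum")
  pred_b <- rational_eval(fb$coef, samples$L, samples$H, "acrylic")
  res <- tibble::tibble(x_A = samples$x_A, x_B = samples$x_B,
                        L = samples$L, H = samples$H,
                        xA_hat = pred_a, xB_hat = pred_b,
                        err_A = pred_a - samples$x_A,
                        err_B = pred_b - samples$x_B)
  fit <- list(residuals = res,
              mae_aluminum = mean(abs(res$err_A)),
              mae_acrylic = mean(abs(res$err_B)),
              max_abs_aluminum = max(abs(res$err_A)),
              max_abs_acrylic = max(abs(res$err_B)),
              iterations = c(aluminum = fa$iterations, acrylic = fb$iterations))
  decomp_model(fa$coef, fb$coef, domain = domain, fit = fit)
}

#' Decompose a low/high sinogram pair into basis-material sinograms
#'
#' Element-wise evaluation of the rational model. Negative thicknesses are
#' preserved (not clipped); their fraction is attached as the
#' `negative_fraction` attribute. Values outside the calibrated domain are
#' allowed (extrapolation) but counted in the `extrapolated_fraction`
#' attribute.
#'
#' @param model a [decomp_model()].
#' @param sino_L,sino_H [sinogram()]s with matching geometry.
#' @param extrapolation out-of-domain policy, see [evaluate_decomposition()].
#' @return A list of two [sinogram()]s, `x_A` (aluminum) and `x_B` (acrylic),
#'   in mm.
#' @export
decompose_sinograms <- function(model, sino_L, sino_H,
                                extrapolation = c("rational", "linear")) {
  if (!same_geometry(sino_L, sino_H)) stop("sinogram geometries differ")
  est <- evaluate_decomposition(model, sino_L$values, sino_H$values,
                                extrapolation = extrapolation)
  out <- list(
    x_A = sinogram(est$x_A, sino_L$geometry, energy = "aluminum", units = "mm"),
    x_B = sinogram(est$x_B, sino_L$geometry, energy = "acrylic", units = "mm"))
  attr(out$x_A, "negative_fraction") <- mean(est$x_A < 0)
  attr(out$x_B, "negative_fraction") <- mean(est$x_B < 0)
  outside <- sino_L$values < model$domain$L[1] |
    sino_L$values > model$domain$L[2] |
    sino_H$values < model$domain$H[1] | sino_H$values > model$domain$H[2]
  attr(out$x_A, "extrapolated_fraction") <- mean(outside)
  out
}

#' Validate the parameterization on wedge projections
#'
#' Estimates the wedge thicknesses from the measured ROI samples and reports
#' the mean absolute error per thickness step: for each aluminum thickness
#' the mean over the acrylic steps, and vice versa.
#'
#' @param model a [decomp_model()].
#' @param proj_L,proj_H wedge projection matrices.
#' @param wedge output of [build_step_wedge()].
#' @return A list with per-thickness error tibbles `aluminum`
#'   (`thickness`, `mae`) and `acrylic`, plus the per-sample table.
#' @export
validate_wedge <- function(model, proj_L, proj_H, wedge) {
  s <- measure_wedge_LH(proj_L, proj_H, wedge)
  est <- evaluate_decomposition(model, s$L, s$H)
  s$err_A <- est$x_A - s$x_A
  s$err_B <- est$x_B - s$x_B
  per_al <- tibble::tibble(
    thickness = sort(unique(s$x_A)),
    mae = vapply(sort(unique(s$x_A)),
                 function(t) mean(abs(s$err_A[s$x_A == t])), 0))
  per_ac <- tibble::tibble(
    thickness = sort(unique(s$x_B)),
    mae = vapply(sort(unique(s$x_B)),
                 function(t) mean(abs(s$err_B[s$x_B == t])), 0))
  list(aluminum = per_al, acrylic = per_ac, samples = tibble::as_tibble(s))
}

#' Serialize / restore a decomposition model as JSON
#' @param model a [decomp_model()].
#' @param path JSON file path.
#' @export
write_decomp_model <- function(model, path) {
  jsonlite::write_json(list(coef_aluminum = model$coef_aluminum,
                            coef_acrylic = model$coef_acrylic,
                            domain = model$domain),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_decomp_model
#' @export
read_decomp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  decomp_model(j$coef_aluminum, j$coef_acrylic,
               domain = list(L = j$domain$L, H = j$domain$H))
}
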