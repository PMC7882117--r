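## Image-quality metrics: RMSE/PSNR between real and pseudo images, CNR,
## coefficient of variation, and evaluation masks.

#' Evaluation mask from phantom support and a field-of-view disk
#'
#' Valid pixels are those inside the phantom support AND inside the
#' field-of-view disk, so truncated regions of the high-energy scan and air
#' outside the phantom are excluded from metric computation.
#'
#' @param support logical matrix: phantom support (e.g. [map_support()] or
#'   `unclass(img) > -300`).
#' @param fov_mm field-of-view diameter in mm (e.g. 330 for the high-energy
#'   scan); `Inf` for no restriction.
#' @param spacing pixel size in mm.
#' @return An `evaluation_mask`: logical matrix with the provenance recorded.
#' @export
make_mask <- function(support, fov_mm, spacing) {
  stopifnot(is.logical(support), is.matrix(support))
  if (!any(support)) stop("phantom support is empty")
  cx <- img_coords(nrow(support), spacing)
  cy <- img_coords(ncol(support), spacing)
  fov <- outer(cx^2, cy^2, "+") <= (fov_mm / 2)^2
  m <- support & fov
  if (!any(m)) stop("mask is empty: support and field of view do not intersect")
  structure(m, class = c("evaluation_mask", "matrix"),
            fov_mm = fov_mm, spacing = spacing)
}

#' RMSE and PSNR between two images
#'
#' `RMSE = sqrt(mean((real - pseudo)^2))` over the masked pixels and
#' `PSNR = 20 log10(I_max / RMSE)` with `I_max` the fixed display-range
#' maximum (default 3095, the upper end of the 12-bit HU scale shifted by
#' +1024). Identical images give `PSNR = Inf`.
#'
#' @param real,pseudo [ct_image()]s (or matrices) on the same grid.
#' @param mask optional logical matrix / [make_mask()]; defaults to all
#'   pixels.
#' @param i_max peak intensity used in the PSNR.
#' @return A tibble with columns `rmse`, `psnr`, `n_pixels`, `i_max`.
#' @export
rmse_psnr <- function(real, pseudo, mask = NULL, i_max = 3095) {
  a <- unclass(real); b <- unclass(pseudo)
  if (!all(dim(a) == dim(b))) stop("images are on different grids")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  m <- as.logical(mask)
  if (!any(m)) stop("empty evaluation mask")
  rmse <- sqrt(mean((a[m] - b[m])^2))
  tibble::tibble(rmse = rmse,
                 psnr = if (rmse == 0) Inf else 20 * log10(i_max / rmse),
                 n_pixels = sum(m), i_max = i_max)
}

#' Contrast-to-noise ratio of a region of interest
#'
#' `(mean(ROI) - mean(background)) / sd(background)` with the sample (n-1)
#' standard deviation.
#'
#' @param img a [ct_image()].
#' @param roi,bg_roi length-3 numeric `(x, y, r)` in mm: the material ROI and
#'   the background ROI (must be disjoint).
#' @return The CNR (scalar).
#' @export
cnr <- function(img, roi, bg_roi) {
  if (sqrt(sum((roi[1:2] - bg_roi[1:2])^2)) < roi[3] + bg_roi[3]) {
    stop("ROI and background ROI overlap")
  }
  s <- roi_sd(img, bg_roi[1], bg_roi[2], bg_roi[3])
  if (s == 0) stop("background standard deviation is zero")
  (roi_mean(img, roi[1], roi[2], roi[3]) -
      roi_mean(img, bg_roi[1], bg_roi[2], bg_roi[3])) / s
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; used to summarize how a
#' syringe's CT number varies across phantom sizes.
#'
#' @param values numeric vector, length at least 2, non-zero mean.
#' @return `sd(values) / mean(values)`.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: coefficient of variation undefined")
  stats::sd(values) / m
}
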