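## Parallel-beam tomography: Siddon ray tracing, forward projection, the
## matched ray-driven adjoint, and filtered backprojection.

#' Parallel-beam acquisition geometry
#'
#' @param n_views number of projection angles.
#' @param n_bins number of detector bins per view.
#' @param pitch detector bin spacing in mm.
#' @param angular_range total angular coverage in radians (pi for the standard
#'   half rotation); views are equispaced on `[0, angular_range)`.
#' @return A `ct_geometry` object.
#' @export
parallel_geometry <- function(n_views, n_bins, pitch, angular_range = pi) {
  stopifnot(n_views >= 1, n_bins >= 1, pitch > 0, angular_range > 0)
  structure(list(n_views = n_views, n_bins = n_bins, pitch = pitch,
                 angular_range = angular_range,
                 angles = seq(0, angular_range, length.out = n_views + 1)[1:n_views]),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("<ct_geometry> parallel beam, %d views over %.0f deg, %d bins @ %.3g mm\n",
              x$n_views, x$angular_range * 180 / pi, x$n_bins, x$pitch))
  invisible(x)
}

#' Sinogram container
#'
#' Line-integral data (`n_views` x `n_bins`) plus its geometry and an energy
#' tag: kVp for polychromatic data, keV for monochromatic/virtual data, or a
#' basis-material name for decomposed thickness sinograms.
#'
#' @param values numeric matrix, `n_views` x `n_bins`.
#' @param geometry a [parallel_geometry()].
#' @param energy energy tag (kVp or keV, numeric) or basis-material name.
#' @param units description of the values (default dimensionless
#'   `-ln(I/I0)`; decomposed sinograms carry `"mm"`).
#' @return A `sinogram` object.
#' @export
sinogram <- function(values, geometry, energy = NULL, units = "-ln(I/I0)") {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_bins) {
    stop("sinogram shape does not match geometry")
  }
  structure(list(values = values, geometry = geometry, energy = energy,
                 units = units),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d bins [%s]",
              nrow(x$values), ncol(x$values), x$units))
  if (!is.null(x$energy)) cat(", energy tag:", format(x$energy))
  cat("\n")
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$geometry[c("n_views", "n_bins", "pitch", "angular_range")],
                   b$geometry[c("n_views", "n_bins", "pitch", "angular_range")]))
}

#' Write / read a sinogram as a portable text container
#' @param sino a [sinogram()].
#' @param path file path for the TSV values (geometry goes to `<path>.json`).
#' @export
write_sinogram <- function(sino, path) {
  utils::write.table(sino$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(n_views = sino$geometry$n_views, n_bins = sino$geometry$n_bins,
               pitch = sino$geometry$pitch,
               angular_range = sino$geometry$angular_range,
               energy = sino$energy, units = sino$units)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- parallel_geometry(meta$n_views, meta$n_bins, meta$pitch,
                            meta$angular_range)
  sinogram(vals, geom, energy = meta$energy, units = meta$units)
}

#' Siddon ray trace through a pixel grid
#'
#' Exact intersection lengths of one ray with every pixel it traverses.
#' The grid is isocentered: `nx` x `ny` pixels of size `spacing` mm.
#'
#' @param origin length-2 numeric, a point on the ray (mm).
#' @param direction length-2 numeric, ray direction (any non-zero length).
#' @param nx,ny grid dimensions in pixels.
#' @param spacing pixel size in mm.
#' @return A list with `index` (1-based linear indices into the image matrix,
#'   column-major) and `length` (mm). Empty vectors if the ray misses the grid.
#' @export
siddon_trace <- function(origin, direction, nx, ny, spacing) {
  cpp_siddon_trace(origin[1], origin[2], direction[1], direction[2],
                   nx, ny, spacing, spacing,
                   -nx * spacing / 2, -ny * spacing / 2)
}

#' Forward project an attenuation image
#'
#' Siddon line integrals of a `mm^-1` image over a parallel-beam geometry;
#' an exactly linear operator.
#'
#' @param img a [ct_image()] in `mm^-1` (or a bare matrix, taken at face
#'   value with `spacing` required).
#' @param geometry a [parallel_geometry()].
#' @param spacing pixel spacing override when `img` is a bare matrix.
#' @return A [sinogram()] whose values are in `mm^-1 * mm` (dimensionless).
#' @export
forward_project <- function(img, geometry, spacing = NULL) {
  if (inherits(img, "ct_image")) {
    if (!identical(img_units(img), "mm^-1")) {
      stop("forward projection expects an image in mm^-1")
    }
    spacing <- img_spacing(img)
  }
  if (is.null(spacing)) stop("spacing required for bare matrices")
  vals <- cpp_forward_project(unclass(img), geometry$angles,
                              geometry$n_bins, geometry$pitch, spacing)
  energy <- if (inherits(img, "ct_image")) {
    e <- attr(img, "energy_kev")
    if (is.null(e)) attr(img, "kvp") else e
  }
  sinogram(vals, geometry, energy = energy)
}

#' Ray-driven backprojection (exact adjoint of [forward_project()])
#'
#' @param sino a [sinogram()].
#' @param nx,ny output grid dimensions in pixels.
#' @param spacing output pixel size in mm.
#' @return A plain matrix: the transpose of the projection operator applied
#'   to the sinogram values.
#' @export
backproject <- function(sino, nx, ny, spacing) {
  cpp_backproject_ray(sino$values, sino$geometry$angles, sino$geometry$pitch,
                      nx, ny, spacing)
}

ramp_filter <- function(npad, pitch, filter = c("shepp-logan", "ram-lak", "hann")) {
  filter <- match.arg(filter)
  k <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  f <- k / (npad * pitch)             # cycles/mm
  fmax <- 1 / (2 * pitch)
  h <- abs(f)
  w <- switch(filter,
    "ram-lak" = rep(1, npad),
    "shepp-logan" = {
      u <- pi * f / (2 * fmax)
      ifelse(u == 0, 1, sin(u) / u)
    },
    "hann" = 0.5 * (1 + cos(pi * f / fmax)))
  h * w * (abs(f) <= fmax)
}

#' Filtered backprojection reconstruction
#'
#' Standard parallel-beam FBP: frequency-domain ramp filtering of each view
#' (apodized by the chosen window, zero-padded to reduce wrap-around),
#' pixel-driven backprojection, and the `angular_range / n_views` angular
#' quadrature weight.
#'
#' @param sino a [sinogram()] of line integrals.
#' @param n output grid size in pixels (`n` x `n`).
#' @param spacing output pixel size in mm (defaults to the detector pitch).
#' @param filter reconstruction filter: `"shepp-logan"` (default, the apodized
#'   analog of a medium-smooth clinical kernel), `"ram-lak"`, or `"hann"`.
#' @return A [ct_image()] in `mm^-1` carrying the sinogram's energy tag.
#' @export
fbp_reconstruct <- function(sino, n, spacing = NULL,
                            filter = c("shepp-logan", "ram-lak", "hann")) {
  filter <- match.arg(filter)
  geom <- sino$geometry
  if (geom$n_views < 2) stop("FBP needs at least 2 views")
  if (is.null(spacing)) spacing <- geom$pitch
  nbins <- geom$n_bins
  npad <- 2^ceiling(log2(2 * nbins))
  p <- rbind(t(sino$values), matrix(0, npad - nbins, geom$n_views))
  h <- ramp_filter(npad, geom$pitch, filter)
  q <- Re(stats::mvfft(stats::mvfft(p) * h, inverse = TRUE)) / npad
  q <- t(q[seq_len(nbins), , drop = FALSE])
  bp <- cpp_backproject_pixel(q, geom$angles, geom$pitch, n, n, spacing)
  vals <- bp * geom$angular_range / geom$n_views
  out <- ct_image(vals, spacing = spacing, units = "mm^-1")
  attr(out, "energy_tag") <- sino$energy
  out
}
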