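#' 2-D CT image container
#'
#' A `ct_image` is a numeric matrix of pixel values plus the minimal geometry
#' and physics metadata the workflow needs: isotropic pixel spacing, the value
#' units (Hounsfield units or linear attenuation in mm^-1), and an energy tag
#' (tube potential in kVp for polychromatic scans, or a monochromatic energy
#' in keV for virtual monochromatic images). The image is centered on the
#' isocenter: pixel `[i, j]` has center coordinates
#' `x = (i - (nx + 1) / 2) * spacing`, `y = (j - (ny + 1) / 2) * spacing`.
#'
#' @param values numeric matrix of pixel values.
#' @param spacing isotropic pixel spacing in mm.
#' @param units value units: `"HU"`, `"mm^-1"`, `"mg/ml"`, or another
#'   descriptive string.
#' @param kvp tube potential tag (numeric, optional).
#' @param energy_kev monochromatic energy tag in keV (optional).
#' @param fov_mm reconstruction field-of-view diameter in mm (optional).
#' @param provenance free-form provenance tag, e.g. `"real-DECT"` or
#'   `"pseudo-DECT"`.
#' @return A `ct_image` object.
#' @export
ct_image <- function(values, spacing, units = "HU", kvp = NULL,
                     energy_kev = NULL, fov_mm = NULL, provenance = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), spacing > 0,
            is.character(units), length(units) == 1)
  structure(values,
            class = c("ct_image", "matrix"),
            spacing = spacing, units = units, kvp = kvp,
            energy_kev = energy_kev, fov_mm = fov_mm,
            provenance = provenance)
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d px, %.4g mm/px, units %s",
              nrow(x), ncol(x), attr(x, "spacing"), attr(x, "units")))
  if (!is.null(attr(x, "kvp"))) cat(sprintf(", %g kVp", attr(x, "kvp")))
  if (!is.null(attr(x, "energy_kev"))) {
    cat(sprintf(", %g keV", attr(x, "energy_kev")))
  }
  if (!is.null(attr(x, "provenance"))) cat(", ", attr(x, "provenance"), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.ct_image <- function(x, window = NULL, ...) {
  v <- unclass(x)
  if (!is.null(window)) v <- pmin(pmax(v, window[1]), window[2])
  graphics::image(z = v, col = grey.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

img_spacing <- function(img) attr(img, "spacing")
img_units <- function(img) attr(img, "units")

## pixel-center coordinate vectors (mm, isocentered)
img_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

with_values <- function(img, values, units = img_units(img), ...) {
  dots <- list(...)
  out <- ct_image(values, spacing = img_spacing(img), units = units,
                  kvp = attr(img, "kvp"), energy_kev = attr(img, "energy_kev"),
                  fov_mm = attr(img, "fov_mm"),
                  provenance = attr(img, "provenance"))
  for (nm in names(dots)) attr(out, nm) <- dots[[nm]]
  out
}

#' Write / read a CT image as a portable text container
#'
#' Values go to a tab-separated file; spacing, units and energy tags go to a
#' JSON sidecar (`<path>.json`), so a series survives plain-text storage.
#'
#' @param img a [ct_image()].
#' @param path file path for the TSV values.
#' @return `write_ct_image` returns `path` invisibly; `read_ct_image` returns
#'   the restored [ct_image()].
#' @export
write_ct_image <- function(img, path) {
  utils::write.table(unclass(img), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(spacing = img_spacing(img), units = img_units(img),
               kvp = attr(img, "kvp"), energy_kev = attr(img, "energy_kev"),
               fov_mm = attr(img, "fov_mm"),
               provenance = attr(img, "provenance"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ct_image(vals, spacing = meta$spacing, units = meta$units, kvp = meta$kvp,
           energy_kev = meta$energy_kev, fov_mm = meta$fov_mm,
           provenance = meta$provenance)
}

#' Mean pixel value inside a circular region of interest
#'
#' @param img a [ct_image()].
#' @param x,y ROI center in mm (isocentered coordinates).
#' @param r ROI radius in mm.
#' @return Mean of the pixels whose centers fall inside the disk.
#' @export
roi_mean <- function(img, x, y, r) {
  m <- roi_disk_mask(img, x, y, r)
  if (!any(m)) stop("ROI contains no pixels")
  mean(unclass(img)[m])
}

#' @rdname roi_mean
#' @export
roi_sd <- function(img, x, y, r) {
  m <- roi_disk_mask(img, x, y, r)
  if (sum(m) < 2) stop("ROI needs at least 2 pixels")
  stats::sd(unclass(img)[m])
}

roi_disk_mask <- function(img, x, y, r) {
  sp <- img_spacing(img)
  cx <- img_coords(nrow(img), sp)
  cy <- img_coords(ncol(img), sp)
  outer(cx - x, cy - y, function(a, b) a^2 + b^2) <= r^2
}
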