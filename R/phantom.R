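## Digital phantoms: calibration phantoms (five sizes), evaluation phantoms
## (Ephan1/Ephan2), rasterization to material maps, and the calibration
## step wedge.

#' Phantom specification
#'
#' A phantom is an ordered list of layers drawn over air: each later layer
#' overwrites the earlier ones where it covers them. The first layer is the
#' outer shape; rods and syringes follow.
#'
#' @param name phantom name.
#' @param layers a data frame with columns `shape` ("circle" or "ellipse"),
#'   `x`, `y` (center, mm), `rx`, `ry` (semi-axes, mm), `material`, `role`
#'   ("outer", "base", "rod", "syringe") and `conc` (iodine mg/ml, NA
#'   otherwise).
#' @param bg_roi numeric matrix with columns `(x, y, r)`, one row per
#'   background region guaranteed to contain only base material; background
#'   subtraction averages over them.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(name, layers, bg_roi = NULL) {
  stopifnot(all(c("shape", "x", "y", "rx", "ry", "material", "role", "conc")
                %in% names(layers)))
  shell <- layers[1, ]
  ins <- layers[layers$role %in% c("rod", "syringe"), ]
  if (nrow(ins) > 1) {
    ## inserts must be pairwise non-overlapping (circles)
    d <- as.matrix(stats::dist(cbind(ins$x, ins$y)))
    lim <- outer(ins$rx, ins$rx, "+")
    diag(d) <- Inf
    if (any(d < lim)) stop("phantom inserts overlap")
  }
  if (nrow(ins) > 0) {
    ## ... and lie inside the outer shape
    inside <- (ins$x / (shell$rx - ins$rx))^2 +
      (ins$y / (shell$ry - ins$rx))^2 <= 1
    if (!all(inside)) stop("phantom inserts extend outside the outer shape")
  }
  structure(list(name = name, layers = layers, bg_roi = bg_roi),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  ins <- x$layers[x$layers$role %in% c("rod", "syringe"), ]
  cat(sprintf("<phantom_spec> %s: outer %s %.0f x %.0f mm, %d inserts (%d syringes)\n",
              x$name, x$layers$shape[1], 2 * x$layers$rx[1], 2 * x$layers$ry[1],
              nrow(ins), sum(ins$role == "syringe")))
  invisible(x)
}

#' Insert table of a phantom
#' @param spec a [phantom_spec()].
#' @return A tibble of the rod/syringe inserts (center, radius, material,
#'   role, iodine concentration).
#' @export
phantom_inserts <- function(spec) {
  tibble::as_tibble(spec$layers[spec$layers$role %in% c("rod", "syringe"),
                                c("x", "y", "rx", "material", "role", "conc")])
}

layer_row <- function(shape, x, y, rx, ry, material, role, conc = NA_real_) {
  data.frame(shape = shape, x = x, y = y, rx = rx, ry = ry,
             material = material, role = role, conc = conc,
             stringsAsFactors = FALSE)
}

#' Study iodine concentrations (mg/ml)
#' @export
iodine_concentrations <- function() c(2.19, 4.38, 8.75, 17.5, 35)

#' Digital calibration phantom
#'
#' An 18-cm soft-tissue-equivalent disk housing 4 tissue rods (adipose,
#' breast, muscle, liver) and 5 iodine syringes (2-cm diameter, 2.19 to
#' 35 mg/ml) on a 55-mm ring, wrapped in tissue-equivalent bolus annuli
#' (2.5-cm layers) to reach the requested overall diameter.
#'
#' @param size_cm overall diameter in cm: 18, 23, 28, 33 or 38.
#' @return A [phantom_spec()].
#' @export
build_calibration_phantom <- function(size_cm) {
  if (!size_cm %in% c(18, 23, 28, 33, 38)) {
    stop("calibration phantom size must be one of 18, 23, 28, 33, 38 cm")
  }
  r_out <- size_cm * 10 / 2
  layers <- layer_row("circle", 0, 0, r_out, r_out,
                      if (size_cm > 18) "bolus" else "soft_tissue_base",
                      "outer")
  if (size_cm > 18) {
    layers <- rbind(layers,
                    layer_row("circle", 0, 0, 90, 90, "soft_tissue_base", "base"))
  }
  ang <- seq(0, 320, by = 40) * pi / 180
  px <- 55 * cos(ang); py <- 55 * sin(ang)
  rods <- c("adipose", "breast", "muscle", "liver")
  conc <- iodine_concentrations()
  for (k in 1:9) {
    if (k %% 2 == 1 && k < 9) {
      layers <- rbind(layers, layer_row("circle", px[k], py[k], 12.5, 12.5,
                                        rods[(k + 1) / 2], "rod"))
    } else {
      i <- if (k == 9) 5 else k / 2
      layers <- rbind(layers, layer_row("circle", px[k], py[k], 10, 10,
                                        iodine_solution_name(conc[i]),
                                        "syringe", conc[i]))
    }
  }
  ## background ROIs: center plus an outer-annulus ring, all clear of inserts
  bg_ang <- (20 + 90 * 0:3) * pi / 180
  phantom_spec(sprintf("Cphan_%dcm", size_cm), layers,
               bg_roi = rbind(c(0, 0, 12),
                              cbind(78 * cos(bg_ang), 78 * sin(bg_ang), 6)))
}

#' Digital evaluation phantoms
#'
#' 330 x 270 mm elliptical epoxy-base phantoms. `Ephan1` houses 17 tissue rods
#' including lung (inhale 0.195, exhale 0.51 g/cc), plastic water, trabecular
#' and dense bone; `Ephan2` houses 12 tissue rods plus the 5 iodine syringes.
#'
#' @param which `"Ephan1"` or `"Ephan2"`.
#' @return A [phantom_spec()].
#' @export
build_evaluation_phantom <- function(which = c("Ephan1", "Ephan2")) {
  which <- match.arg(which)
  layers <- layer_row("ellipse", 0, 0, 165, 135, "soft_tissue_base", "outer")
  tissues <- c("lung_inhale", "lung_exhale", "adipose", "breast",
               "plastic_water", "muscle", "liver", "trabecular_bone",
               "dense_bone")
  out_ang <- seq(0, 330, by = 30) * pi / 180
  in_ang <- c(45, 135, 225, 315) * pi / 180
  pos <- rbind(cbind(110 * cos(out_ang), 110 * sin(out_ang)),
               cbind(55 * cos(in_ang), 55 * sin(in_ang)),
               c(0, 0))
  if (which == "Ephan1") {
    mats <- rep_len(tissues, 17)
    for (k in 1:17) {
      layers <- rbind(layers, layer_row("circle", pos[k, 1], pos[k, 2],
                                        12.5, 12.5, mats[k], "rod"))
    }
  } else {
    mats <- rep_len(tissues, 12)
    for (k in 1:12) {
      layers <- rbind(layers, layer_row("circle", pos[k, 1], pos[k, 2],
                                        12.5, 12.5, mats[k], "rod"))
    }
    conc <- iodine_concentrations()
    for (k in 1:5) {
      layers <- rbind(layers, layer_row("circle", pos[12 + k, 1], pos[12 + k, 2],
                                        10, 10, iodine_solution_name(conc[k]),
                                        "syringe", conc[k]))
    }
  }
  bg_ang <- (15 + 90 * 0:3) * pi / 180
  phantom_spec(which, layers,
               bg_roi = cbind(82.5 * cos(bg_ang), 82.5 * sin(bg_ang), 8))
}

## coverage fraction of an ellipse over the pixel grid, by subpixel sampling
shape_coverage <- function(cx, cy, rx, ry, xc, yc, spacing, supersample) {
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * spacing
  acc <- matrix(0, length(xc), length(yc))
  for (ox in off) {
    u2 <- ((xc + ox - cx) / rx)^2
    for (oy in off) {
      v2 <- ((yc + oy - cy) / ry)^2
      acc <- acc + (outer(u2, v2, "+") <= 1)
    }
  }
  acc / supersample^2
}

#' Rasterize a phantom onto a material map
#'
#' Anti-aliased rasterization: each layer's per-pixel coverage fraction is
#' estimated on a subpixel grid, and layers composite in order (later layers
#' replace earlier material in proportion to their coverage), so boundary
#' pixels carry partial-volume fractions that sum to 1.
#'
#' @param spec a [phantom_spec()].
#' @param n grid size in pixels (`n` x `n`).
#' @param spacing pixel size in mm.
#' @param supersample subpixel sampling factor per axis (default 8).
#' @return A `material_map`: list with `materials`, `fractions`
#'   (`n` x `n` x n_materials array), `spacing`, and the source spec.
#' @export
rasterize <- function(spec, n, spacing, supersample = 8) {
  half <- n * spacing / 2
  outer_l <- spec$layers[1, ]
  if (outer_l$rx > half || outer_l$ry > half) {
    stop("phantom exceeds the requested grid")
  }
  xc <- img_coords(n, spacing)
  mats <- unique(c("air", spec$layers$material))
  fr <- array(0, c(n, n, length(mats)), dimnames = list(NULL, NULL, mats))
  fr[, , "air"] <- 1
  for (k in seq_len(nrow(spec$layers))) {
    ly <- spec$layers[k, ]
    cov <- shape_coverage(ly$x, ly$y, ly$rx, ly$ry, xc, xc, spacing, supersample)
    fr <- fr * rep(1 - cov, length(mats))
    fr[, , ly$material] <- fr[, , ly$material] + cov
  }
  structure(list(materials = mats, fractions = fr, spacing = spacing,
                 n = n, spec = spec),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  cat(sprintf("<material_map> %d x %d px @ %.3g mm, materials: %s\n",
              x$n, x$n, x$spacing, paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Phantom support mask of a material map
#' @param map a `material_map`.
#' @return Logical matrix: pixels with less than 50% air.
#' @export
map_support <- function(map) map$fractions[, , "air"] < 0.5

## ---- calibration step wedge ------------------------------------------------

#' Step-wedge specification
#'
#' Aluminum and acrylic step wedges stacked orthogonally, so every
#' (aluminum, acrylic) thickness combination appears as a rectangle in the
#' projection.
#'
#' @param aluminum_mm aluminum step thicknesses (mm), non-negative increasing.
#' @param acrylic_mm acrylic step thicknesses (mm), non-negative increasing.
#' @return A `wedge_spec` object.
#' @export
wedge_spec <- function(aluminum_mm = c(0, 6, 12, 18, 24, 30),
                       acrylic_mm = c(5, 10, 15, 20, 25, 30, 35, 40)) {
  for (v in list(aluminum_mm, acrylic_mm)) {
    if (any(v < 0) || any(diff(v) <= 0)) {
      stop("wedge thicknesses must be non-negative and increasing")
    }
  }
  structure(list(aluminum_mm = aluminum_mm, acrylic_mm = acrylic_mm),
            class = "wedge_spec")
}

#' Projection-domain thickness maps of the step wedge
#'
#' Builds the orthogonal layout: aluminum thickness varies along rows,
#' acrylic thickness along columns, each step a band of `band_px` pixels.
#' ROI rectangles are centered in each combination cell with a margin of at
#' least 2 pixels from every step boundary.
#'
#' @param spec a [wedge_spec()].
#' @param band_px band width per step in pixels.
#' @param margin_px ROI margin from the step boundaries in pixels.
#' @return A list with thickness maps `x_A`, `x_B` (matrices, mm), the ROI
#'   table (`rois`: one row per combination with pixel bounds), and the spec.
#' @export
build_step_wedge <- function(spec = wedge_spec(), band_px = 16, margin_px = 3) {
  stopifnot(margin_px >= 2, band_px > 2 * margin_px + 1)
  na <- length(spec$aluminum_mm); nb <- length(spec$acrylic_mm)
  x_A <- matrix(rep(spec$aluminum_mm, each = band_px), na * band_px, nb * band_px)
  x_B <- matrix(rep(spec$acrylic_mm, each = band_px), na * band_px, nb * band_px,
                byrow = TRUE)
  rois <- expand.grid(ia = seq_len(na), ib = seq_len(nb))
  rois <- tibble::tibble(
    x_A = spec$aluminum_mm[rois$ia],
    x_B = spec$acrylic_mm[rois$ib],
    i0 = (rois$ia - 1) * band_px + margin_px + 1,
    i1 = rois$ia * band_px - margin_px,
    j0 = (rois$ib - 1) * band_px + margin_px + 1,
    j1 = rois$ib * band_px - margin_px)
  list(x_A = x_A, x_B = x_B, rois = rois, spec = spec, band_px = band_px)
}

#' Simulate a polychromatic projection of the step wedge
#'
#' Beer-Lambert transmission through the aluminum/acrylic thickness maps for
#' each spectrum bin, with optional Poisson counting noise per detector pixel.
#'
#' @param wedge output of [build_step_wedge()].
#' @param spectrum a [generate_spectrum()] beam.
#' @param photons_per_pixel expected photon count per detector pixel.
#' @param noise apply Poisson noise.
#' @param seed RNG seed for the noise.
#' @param bhc apply the scanner-standard water beam-hardening precorrection
#'   ([water_precorrect()]), so wedge projections come through the same
#'   measurement chain as the phantom scans they calibrate.
#' @return Matrix of projection values `-ln(I/I0)`.
#' @export
simulate_wedge_projection <- function(wedge, spectrum, photons_per_pixel = 1e5,
                                      noise = TRUE, seed = NULL, bhc = TRUE) {
  mu_al <- attenuation_coefficient("aluminum", spectrum$energy_kev)
  mu_ac <- attenuation_coefficient("acrylic", spectrum$energy_kev)
  w <- spectrum$fluence
  T <- matrix(0, nrow(wedge$x_A), ncol(wedge$x_A))
  for (e in which(w > 1e-12)) {
    T <- T + w[e] * exp(-mu_al[e] * wedge$x_A - mu_ac[e] * wedge$x_B)
  }
  p <- if (!noise) {
    -log(T)
  } else {
    run <- function() {
      counts <- matrix(stats::rpois(length(T), photons_per_pixel * T), nrow(T))
      counts[counts == 0] <- 0.5   # half-count floor for empty bins
      -log(counts / photons_per_pixel)
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  }
  if (bhc) water_precorrect(p, spectrum) else p
}

#' Measure calibration samples from wedge projections
#'
#' One sample per (aluminum, acrylic) thickness combination: `L` and `H` are
#' the mean projection values inside the combination's ROI.
#'
#' @param proj_L,proj_H projection matrices at the low and high energy.
#' @param wedge output of [build_step_wedge()].
#' @return A tibble of calibration samples (`x_A`, `x_B`, `L`, `H`).
#' @export
measure_wedge_LH <- function(proj_L, proj_H, wedge) {
  r <- wedge$rois
  if (max(r$i1) > nrow(proj_L) || max(r$j1) > ncol(proj_L) ||
      max(r$i1) > nrow(proj_H) || max(r$j1) > ncol(proj_H)) {
    stop("ROI extends outside the projection")
  }
  roi_mean_rect <- function(p, k) {
    mean(p[r$i0[k]:r$i1[k], r$j0[k]:r$j1[k]])
  }
  tibble::tibble(
    x_A = r$x_A, x_B = r$x_B,
    L = vapply(seq_len(nrow(r)), function(k) roi_mean_rect(proj_L, k), 0),
    H = vapply(seq_len(nrow(r)), function(k) roi_mean_rect(proj_H, k), 0))
}

#' Write / read a phantom specification as JSON
#'
#' Structured-text round trip of the layer table and background ROIs, so
#' phantom definitions can live outside R code.
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(list(name = spec$name, layers = spec$layers,
                            bg_roi = spec$bg_roi),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- as.data.frame(j$layers)
  if (!"conc" %in% names(layers)) layers$conc <- NA_real_
  layers$conc <- as.numeric(layers$conc)
  phantom_spec(j$name, layers,
               bg_roi = if (!is.null(j$bg_roi)) as.matrix(j$bg_roi))
}
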