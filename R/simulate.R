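## Polychromatic CT acquisition simulation: Beer-Lambert transmission per
## spectrum bin through the rasterized material map, Poisson counting noise,
## and FBP reconstruction to HU.

#' Default photons per ray for a tube potential
#'
#' Baseline 1e5 photons/ray at 120 kVp, scaled by the study's effective
#' tube current-time products (282 / 175 / 120 mAs at 80 / 120 / 140 kVp).
#'
#' @param kvp tube potential.
#' @return Expected unattenuated photon count per detector ray.
#' @export
default_photons <- function(kvp) {
  mas <- c("80" = 282, "120" = 175, "140" = 120)
  unname(1e5 * mas[as.character(kvp)] / 175)
}

#' Default scan geometry for a reconstruction grid
#'
#' @param n image grid size (pixels).
#' @param spacing pixel size in mm (detector pitch matches it).
#' @param n_views number of views over 180 degrees (default 1.5 per pixel,
#'   at least 96).
#' @return A [parallel_geometry()] whose detector covers the grid width.
#' @export
scan_geometry <- function(n, spacing, n_views = max(96L, round(1.5 * n))) {
  parallel_geometry(n_views, n_bins = n + 9, pitch = spacing)
}

#' Simulate a polychromatic sinogram of a material map
#'
#' Per ray: path length through every material via Siddon tracing of the
#' partial-volume fraction maps, transmitted fraction
#' `T = sum_E w(E) exp(-sum_m mu_m(E) l_m)`, detected counts
#' `Poisson(photons_per_ray * T)` when noise is on (zero counts floored at
#' half a count), and the stored value `-ln(I/I0)`.
#'
#' @param map a `material_map` from [rasterize()].
#' @param spectrum a [generate_spectrum()] or [monochromatic_spectrum()] beam.
#' @param geometry a [parallel_geometry()].
#' @param photons_per_ray expected unattenuated counts per ray.
#' @param noise apply Poisson noise.
#' @param seed RNG seed for the noise.
#' @return A [sinogram()] tagged with the spectrum's kVp.
#' @export
simulate_polychromatic_sinogram <- function(map, spectrum, geometry,
                                            photons_per_ray = 1e5,
                                            noise = TRUE, seed = NULL) {
  stopifnot(photons_per_ray > 0)
  lens <- lapply(map$materials, function(m) {
    cpp_forward_project(map$fractions[, , m], geometry$angles,
                        geometry$n_bins, geometry$pitch, map$spacing)
  })
  if (!all(vapply(lens, function(l) all(is.finite(l)), logical(1)))) {
    stop("non-finite path lengths in projection")
  }
  w <- spectrum$fluence
  mus <- vapply(map$materials,
                function(m) attenuation_coefficient(m, spectrum$energy_kev),
                numeric(length(spectrum$energy_kev)))
  T <- matrix(0, geometry$n_views, geometry$n_bins)
  for (e in which(w > 1e-12)) {
    A <- 0
    for (m in seq_along(lens)) A <- A + mus[e, m] * lens[[m]]
    T <- T + w[e] * exp(-A)
  }
  vals <- if (noise) {
    run <- function() {
      counts <- matrix(stats::rpois(length(T), photons_per_ray * T), nrow(T))
      counts[counts == 0] <- 0.5
      -log(counts / photons_per_ray)
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  } else {
    -log(T)
  }
  sinogram(vals, geometry, energy = spectrum$kvp)
}

#' Simulate a CT scan of a phantom
#'
#' Rasterize, acquire a polychromatic sinogram, reconstruct with FBP, and
#' convert to HU at the tube potential's effective energy. All potentials are
#' reconstructed on a common 50-cm field-of-view grid so multi-kVp images of
#' one phantom are co-registered; the 140-kVp image is additionally masked to
#' its 33-cm reconstruction field of view (pixels outside are set to air),
#' emulating the truncation of large phantoms in the high-energy scan.
#'
#' @param spec a [phantom_spec()].
#' @param kvp tube potential: 80, 120 or 140 (140 implies the tin filter).
#' @param grid reconstruction grid size in pixels.
#' @param fov_mm acquisition field of view (mm); pixel size is `fov_mm/grid`.
#' @param noise apply Poisson counting noise.
#' @param seed RNG seed for the noise.
#' @param n_views number of views (default from [scan_geometry()]).
#' @param photons_per_ray photon budget per ray (default [default_photons()]).
#' @param filter FBP filter.
#' @param supersample rasterization subsampling.
#' @param bhc apply the scanner-standard water beam-hardening precorrection
#'   ([water_precorrect()]) to the measured sinogram before reconstruction.
#' @return A [ct_image()] in HU tagged with `kvp`, its effective
#'   field of view (`fov_mm` attribute) and provenance `"real-DECT"`.
#' @export
simulate_ct_scan <- function(spec, kvp, grid = 512, fov_mm = 500,
                             noise = TRUE, seed = NULL, n_views = NULL,
                             photons_per_ray = NULL,
                             filter = "shepp-logan", supersample = 8,
                             bhc = TRUE) {
  if (!kvp %in% c(80, 120, 140)) stop("kvp must be 80, 120 or 140")
  spacing <- fov_mm / grid
  geom <- if (is.null(n_views)) scan_geometry(grid, spacing) else
    parallel_geometry(n_views, grid + 9, spacing)
  if (is.null(photons_per_ray)) photons_per_ray <- default_photons(kvp)
  map <- rasterize(spec, grid, spacing, supersample = supersample)
  spectrum <- generate_spectrum(kvp)
  sino <- simulate_polychromatic_sinogram(map, spectrum, geom,
                                          photons_per_ray = photons_per_ray,
                                          noise = noise, seed = seed)
  if (bhc) {
    sino <- sinogram(water_precorrect(sino$values, spectrum), geom,
                     energy = kvp)
  }
  mu <- fbp_reconstruct(sino, grid, spacing, filter = filter)
  recon_fov <- if (kvp == 140) min(330, fov_mm) else fov_mm
  vals <- unclass(mu)
  cx <- img_coords(grid, spacing)
  outside <- outer(cx^2, cx^2, "+") > (recon_fov / 2)^2
  vals[outside] <- 0                      # air outside the recon support
  mu <- ct_image(vals, spacing = spacing, units = "mm^-1", kvp = kvp,
                 fov_mm = recon_fov, provenance = "real-DECT")
  mu_to_hu(mu)
}
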