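## Attenuation physics: XCOM-derived material tables, polychromatic spectrum
## models, effective energies and HU <-> mu conversion.

.pd_env <- new.env(parent = emptyenv())

#' Attenuation table of the base materials
#'
#' Loads the XCOM-derived mass attenuation knots shipped with the package and
#' interpolates them (log-log) onto a 1-keV energy grid from 10 to 150 keV.
#' K-edges (iodine at 33.17 keV, tin at 29.20 keV) are preserved because the
#' knot list contains a point on each side of the edge.
#'
#' @return A list with `energy_kev` (10:150), `density` (named vector, g/cm^3)
#'   and `mu_over_rho` (matrix, energy x material, cm^2/g).
#' @export
material_table <- function() {
  if (!is.null(.pd_env$material_table)) return(.pd_env$material_table)
  path <- system.file("extdata", "attenuation_xcom.csv", package = "pseudodect")
  raw <- utils::read.csv(path, comment.char = "#")
  grid <- 10:150
  mats <- unique(raw$material)
  mu <- sapply(mats, function(m) {
    sub <- raw[raw$material == m, ]
    loglog_interp(sub$energy_kev, sub$mu_over_rho, grid)
  })
  dens <- vapply(mats, function(m) raw$density_g_cm3[raw$material == m][1],
                 numeric(1))
  tab <- list(energy_kev = grid, density = dens, mu_over_rho = mu)
  .pd_env$material_table <- tab
  tab
}

## log-log linear interpolation; x strictly increasing (edge knots are
## distinct by a small energy offset, so edges survive)
loglog_interp <- function(x, y, xout) {
  stopifnot(all(diff(x) > 0), all(y > 0))
  exp(stats::approx(log(x), log(y), xout = log(xout), rule = 2)$y)
}

## Derived materials: mixtures of the base XCOM entries. Tissue surrogates use
## water composition at the stated nominal density (epoxy compositions are
## proprietary); iodine solutions are water + elemental iodine by mass.
material_registry <- function() {
  if (!is.null(.pd_env$registry)) return(.pd_env$registry)
  base <- material_table()
  reg <- list()
  for (m in colnames(base$mu_over_rho)) {
    reg[[m]] <- list(density = unname(base$density[m]),
                     components = m, fractions = 1)
  }
  waterlike <- function(density) {
    list(density = density, components = "water", fractions = 1)
  }
  reg$air <- waterlike(0.0012)
  reg$soft_tissue_base <- waterlike(1.02)   # epoxy resin base of the phantoms
  reg$bolus <- waterlike(1.02)              # tissue-equivalent bolus annuli
  reg$adipose <- waterlike(0.960)
  reg$breast <- waterlike(0.991)
  reg$muscle <- waterlike(1.062)
  reg$liver <- waterlike(1.072)
  reg$plastic_water <- waterlike(1.016)
  reg$lung_inhale <- waterlike(0.195)
  reg$lung_exhale <- waterlike(0.510)
  reg$trabecular_bone <- waterlike(1.161)
  reg$dense_bone <- waterlike(1.530)
  for (conc in c(2.19, 4.38, 8.75, 17.5, 35)) {
    reg[[iodine_solution_name(conc)]] <- iodine_solution(conc)
  }
  .pd_env$registry <- reg
  reg
}

#' Iodine solution as a water/iodine mixture
#'
#' Volume-additive mixture model: `conc` grams of iodine per ml displace their
#' own volume of water, giving solution density
#' `1 + conc * (1 - 1/rho_I)` and mass fractions by construction.
#'
#' @param conc_mg_ml iodine concentration in mg/ml.
#' @return A registry entry (density + component mass fractions).
#' @export
iodine_solution <- function(conc_mg_ml) {
  c_g <- conc_mg_ml / 1000                      # g iodine per cm^3 solution
  rho_i <- material_table()$density[["iodine"]]
  rho <- 1 + c_g * (1 - 1 / rho_i)
  w_i <- c_g / rho
  list(density = rho, components = c("iodine", "water"),
       fractions = c(w_i, 1 - w_i))
}

iodine_solution_name <- function(conc_mg_ml) {
  paste0("iodine_", format(conc_mg_ml, trim = TRUE))
}

#' Materials known to the package
#' @return Character vector of material names accepted by
#'   [attenuation_coefficient()].
#' @export
list_materials <- function() names(material_registry())

resolve_material <- function(material) {
  reg <- material_registry()
  entry <- reg[[material]]
  if (is.null(entry)) {
    ## dynamic iodine solutions: "iodine_<conc>"
    if (grepl("^iodine_[0-9.]+$", material)) {
      conc <- as.numeric(sub("^iodine_", "", material))
      return(iodine_solution(conc))
    }
    stop("unknown material: ", material)
  }
  entry
}

#' Mass attenuation coefficient of a material
#'
#' @param material a name from [list_materials()] (or `"iodine_<conc>"`).
#' @param energy_kev photon energies in keV, within 10-150.
#' @return Mass attenuation coefficient(s) in cm^2/g, log-log interpolated on
#'   the 1-keV grid.
#' @export
mass_attenuation <- function(material, energy_kev) {
  if (any(energy_kev < 10 | energy_kev > 150)) {
    stop("energy out of the tabulated range 10-150 keV")
  }
  entry <- resolve_material(material)
  tab <- material_table()
  out <- 0
  for (k in seq_along(entry$components)) {
    comp <- tab$mu_over_rho[, entry$components[k]]
    out <- out + entry$fractions[k] *
      loglog_interp(tab$energy_kev, comp, energy_kev)
  }
  out
}

#' Linear attenuation coefficient of a material
#'
#' Density times the mass attenuation coefficient, converted to mm^-1.
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation in mm^-1 (vectorized over `energy_kev`).
#' @export
attenuation_coefficient <- function(material, energy_kev) {
  entry <- resolve_material(material)
  entry$density * mass_attenuation(material, energy_kev) / 10
}

## ---- x-ray spectra ---------------------------------------------------------

#' Polychromatic x-ray spectrum model
#'
#' Analytic tungsten-anode model: Kramers-type bremsstrahlung
#' `n(E) ~ (kVp - E)/E` on a 1-keV grid, tungsten K characteristic lines for
#' tube potentials above the K-shell binding energy (69.5 keV), inherent
#' aluminum filtration, and an optional tin filter (the "Sn 140" beam).
#' The returned fluence is normalized to sum to 1.
#'
#' @param kvp tube potential: 80, 120 or 140.
#' @param tin_filter apply the tin filter (defaults to TRUE at 140 kVp, the
#'   only potential where it is meaningful).
#' @param tin_mm tin filter thickness in mm.
#' @param inherent_al_mm inherent aluminum filtration in mm.
#' @return A `spectrum` object: list with `kvp`, `filtration`, `energy_kev`
#'   (10:150) and `fluence` (zero above the kVp, summing to 1).
#' @export
generate_spectrum <- function(kvp, tin_filter = (kvp == 140), tin_mm = 0.4,
                              inherent_al_mm = 12) {
  if (!kvp %in% c(80, 120, 140)) stop("unsupported kVp: ", kvp)
  if (tin_filter && kvp != 140) stop("tin filter is only used at 140 kVp")
  grid <- 10:150
  n <- ifelse(grid < kvp, (kvp - grid) / grid, 0)
  ## tungsten K lines (Ka2, Ka1, Kb1, Kb2), crude yield scaling with overvoltage
  if (kvp > 69.5) {
    lines <- c(58, 59, 67, 69)
    amps <- c(0.29, 0.50, 0.15, 0.06) * 0.08 * (kvp - 69.5) / 70 * sum(n)
    n[match(lines, grid)] <- n[match(lines, grid)] + amps
  }
  n <- n * exp(-attenuation_coefficient("aluminum", grid) * inherent_al_mm)
  filt <- sprintf("%g mm Al inherent", inherent_al_mm)
  if (tin_filter) {
    n <- n * exp(-attenuation_coefficient("tin", grid) * tin_mm)
    filt <- paste0(filt, sprintf(" + %g mm Sn", tin_mm))
  }
  structure(list(kvp = kvp, filtration = filt, energy_kev = grid,
                 fluence = n / sum(n)),
            class = "spectrum")
}

#' Monochromatic "spectrum" (single energy bin)
#' @param energy_kev the single photon energy in keV.
#' @return A `spectrum` object with all fluence in one bin.
#' @export
monochromatic_spectrum <- function(energy_kev) {
  grid <- 10:150
  n <- as.numeric(grid == round(energy_kev))
  if (sum(n) != 1) stop("energy must round to an integer keV in 10-150")
  structure(list(kvp = energy_kev, filtration = "none", energy_kev = grid,
                 fluence = n),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %g kVp (%s), mean energy %.1f keV\n",
              x$kvp, x$filtration, mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum
#' @param spectrum a `spectrum` object.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy_kev * spectrum$fluence)
}

#' Export a spectrum as CSV
#' @param spectrum a `spectrum` object.
#' @param path output file path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_kev = spectrum$energy_kev,
                              fluence = spectrum$fluence),
                   path, row.names = FALSE)
  invisible(path)
}

## ---- effective energies and HU <-> mu --------------------------------------

#' Effective energy of a tube potential
#'
#' The monochromatic energy used to convert HU to linear attenuation for a
#' given polychromatic beam. Defined self-consistently from the package's own
#' spectrum model: the energy at which water's monochromatic attenuation
#' equals the beam's effective attenuation through a reference water path
#' (default 200 mm, a typical body diameter). Cached per tube potential;
#' override via `options(pseudodect.effective_energies = c("80" = 52, ...))`.
#'
#' @param kvp tube potential (80, 120 or 140; 140 implies the tin filter).
#' @param ref_mm reference water path length in mm.
#' @return Effective energy in keV.
#' @export
effective_energy <- function(kvp, ref_mm = 200) {
  override <- getOption("pseudodect.effective_energies", NULL)
  if (!is.null(override) && as.character(kvp) %in% names(override)) {
    return(unname(override[[as.character(kvp)]]))
  }
  key <- sprintf("eff_%g_%g", kvp, ref_mm)
  if (!is.null(.pd_env[[key]])) return(.pd_env[[key]])
  e <- spectrum_effective_energy(generate_spectrum(kvp), ref_mm)
  .pd_env[[key]] <- e
  e
}

#' @rdname effective_energy
#' @param spectrum a `spectrum` object (for [spectrum_effective_energy()]).
#' @export
spectrum_effective_energy <- function(spectrum, ref_mm = 200) {
  mu_w <- attenuation_coefficient("water", spectrum$energy_kev)
  mu_eff <- -log(sum(spectrum$fluence * exp(-mu_w * ref_mm))) / ref_mm
  fine <- seq(10, 150, by = 0.01)
  mu_fine <- attenuation_coefficient("water", fine)
  fine[which.min(abs(mu_fine - mu_eff))]
}

#' Water beam-hardening precorrection of projection data
#'
#' The standard scanner-side correction: each measured polychromatic value
#' `p = -ln(I/I0)` is mapped to the water thickness that would have produced
#' it and rescaled to the monochromatic line integral at the spectrum's
#' effective energy, `p' = mu_w(E_eff) * g^-1(p)` with
#' `g(t) = -ln(sum_E w(E) exp(-mu_w(E) t))`. Water-only objects then
#' reconstruct without cupping; non-water materials (iodine, aluminum, bone)
#' keep their residual hardening, which is what the two-material
#' decomposition corrects. For a monochromatic spectrum the map is the
#' identity.
#'
#' @param p matrix or vector of measured `-ln(I/I0)` values.
#' @param spectrum the acquiring `spectrum`.
#' @param t_max_mm maximum water path of the lookup table (mm).
#' @return Corrected values, same shape as `p`.
#' @export
water_precorrect <- function(p, spectrum, t_max_mm = 650) {
  mu_w <- attenuation_coefficient("water", spectrum$energy_kev)
  tg <- seq(0, t_max_mm, by = 0.5)
  g <- vapply(tg, function(t) {
    -log(sum(spectrum$fluence * exp(-mu_w * t)))
  }, 0)
  e_eff <- spectrum_effective_energy(spectrum)
  mu_eff <- attenuation_coefficient("water", e_eff)
  t <- stats::approx(g, tg, xout = pmax(p, 0), rule = 2)$y
  ## linear continuation beyond the table with the asymptotic slope
  over <- p > g[length(g)]
  if (any(over)) {
    slope <- (tg[length(tg)] - tg[length(tg) - 1]) /
      (g[length(g)] - g[length(g) - 1])
    t[over] <- tg[length(tg)] + (p[over] - g[length(g)]) * slope
  }
  out <- mu_eff * t
  out[p < 0] <- mu_eff * p[p < 0] / (g[2] / tg[2])  # noise below zero: linear
  dim(out) <- dim(p)
  out
}

#' Convert a CT image between HU and linear attenuation
#'
#' `mu = mu_water(E) * (1 + HU/1000)`, with `E` the monochromatic energy tag
#' of the image if present, otherwise the effective energy of its tube
#' potential. The two functions are exact inverses.
#'
#' @param img a [ct_image()] tagged with its units and kVp (or keV).
#' @return The converted [ct_image()].
#' @export
hu_to_mu <- function(img) {
  if (!identical(img_units(img), "HU")) stop("image is not tagged as HU")
  muw <- water_mu_for(img)
  with_values(img, muw * (1 + unclass(img) / 1000), units = "mm^-1")
}

#' @rdname hu_to_mu
#' @export
mu_to_hu <- function(img) {
  if (!identical(img_units(img), "mm^-1")) stop("image is not tagged as mm^-1")
  muw <- water_mu_for(img)
  with_values(img, 1000 * (unclass(img) / muw - 1), units = "HU")
}

water_mu_for <- function(img) {
  e <- attr(img, "energy_kev")
  if (is.null(e)) {
    kvp <- attr(img, "kvp")
    if (is.null(kvp)) stop("image carries neither a kVp nor a keV tag")
    e <- effective_energy(kvp)
  }
  attenuation_coefficient("water", e)
}
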