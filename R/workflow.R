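## Experiment-level drivers: step-wedge parameterization, real-DECT iodine
## quantification across phantom sizes, the pseudo-DECT train/test study, and
## a resumable end-to-end workflow runner.

#' Step-wedge parameterization experiment
#'
#' Simulates 80-kVp and tin-filtered 140-kVp projections of the orthogonal
#' aluminum/acrylic step wedge with Poisson noise, measures the 48 ROI
#' samples, fits the 16 rational-function coefficients by absolute-error
#' minimization, and validates the estimated thicknesses against truth.
#'
#' @param photons_per_pixel photon budget per detector pixel.
#' @param seed RNG seed (the high-energy projection uses `seed + 1`).
#' @param noise apply Poisson noise.
#' @param wedge a [build_step_wedge()] layout (default study wedge).
#' @return A list: fitted `model`, `validation` (per-thickness error tables),
#'   `samples`, and the max per-thickness mean absolute errors
#'   `max_error_aluminum` / `max_error_acrylic` in mm.
#' @export
wedge_calibration_experiment <- function(photons_per_pixel = 1e5, seed = 1,
                                         noise = TRUE,
                                         wedge = build_step_wedge()) {
  sp_l <- generate_spectrum(80)
  sp_h <- generate_spectrum(140)
  proj_l <- simulate_wedge_projection(wedge, sp_l, photons_per_pixel,
                                      noise = noise, seed = seed)
  proj_h <- simulate_wedge_projection(wedge, sp_h, photons_per_pixel,
                                      noise = noise, seed = seed + 1)
  samples <- measure_wedge_LH(proj_l, proj_h, wedge)
  model <- fit_decomposition(samples)
  validation <- validate_wedge(model, proj_l, proj_h, wedge)
  list(model = model, validation = validation, samples = samples,
       max_error_aluminum = max(validation$aluminum$mae),
       max_error_acrylic = max(validation$acrylic$mae))
}

#' Decompose a co-registered low/high image pair
#'
#' The in-house projection-domain route: both images are restricted to their
#' common reconstruction support (the smaller field of view; pixels outside
#' are set to air) so the low- and high-energy rays describe the same object,
#' converted to mm^-1 at their effective energies, forward projected with
#' Siddon tracing, and decomposed ray-by-ray with the calibrated model.
#'
#' @param img_L,img_H HU [ct_image()]s of the same phantom at the low/high
#'   tube potential.
#' @param model a [decomp_model()].
#' @param geometry optional [parallel_geometry()] (default from
#'   [scan_geometry()]).
#' @param extrapolation out-of-domain policy for the rational model; body
#'   projections lie far outside the wedge-calibrated domain, so the default
#'   here is the `"linear"` continuation (see [evaluate_decomposition()]).
#' @return A list: thickness sinograms `x_A`, `x_B`, the projections
#'   `sino_L`, `sino_H`, and the `geometry`.
#' @export
dect_decompose_images <- function(img_L, img_H, model, geometry = NULL,
                                  extrapolation = "linear") {
  if (!all(dim(img_L) == dim(img_H))) stop("images are not co-registered")
  sp <- img_spacing(img_L)
  if (is.null(geometry)) geometry <- scan_geometry(nrow(img_L), sp)
  fov <- min(attr(img_L, "fov_mm") %||% Inf, attr(img_H, "fov_mm") %||% Inf)
  restrict <- function(img) {
    v <- unclass(img)
    if (is.finite(fov)) {
      cx <- img_coords(nrow(v), sp)
      v[outer(cx^2, cx^2, "+") > (fov / 2)^2] <- -1000
    }
    with_values(img, v)
  }
  mu_l <- hu_to_mu(restrict(img_L))
  mu_h <- hu_to_mu(restrict(img_H))
  sino_l <- forward_project(mu_l, geometry)
  sino_h <- forward_project(mu_h, geometry)
  dec <- decompose_sinograms(model, sino_l, sino_h,
                             extrapolation = extrapolation)
  list(x_A = dec$x_A, x_B = dec$x_B, sino_L = sino_l, sino_H = sino_h,
       geometry = geometry, fov_mm = fov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aluminum-equivalent image and syringe ROI signals
#'
#' Reconstructs the decomposed aluminum-thickness sinogram by FBP and
#' measures the background-subtracted mean signal in each iodine syringe of
#' the phantom. The soft-tissue background is modeled as a quadratic surface
#' fitted to all base-material pixels (phantom support minus a margin around
#' every insert, inside the common field of view) and evaluated at each
#' syringe center, so slowly varying aluminum-equivalent background (residual
#' hardening, extrapolation offsets) is removed regardless of phantom size.
#'
#' @param dec a [dect_decompose_images()] result.
#' @param spec the [phantom_spec()] that was scanned.
#' @param n,spacing reconstruction grid.
#' @param roi_frac syringe ROI radius as a fraction of the syringe radius.
#' @param insert_margin_mm exclusion margin around inserts for the
#'   background fit.
#' @return A list: the aluminum-equivalent `image` and a tibble `values`
#'   (`conc`, `value`) with the fitted background already subtracted.
#' @export
aluminum_roi_signals <- function(dec, spec, n, spacing, roi_frac = 0.6,
                                 insert_margin_mm = 8) {
  img <- fbp_reconstruct(dec$x_A, n, spacing)
  img <- ct_image(unclass(img), spacing = spacing, units = "Al-equivalent")
  ins <- phantom_inserts(spec)
  syr <- ins[ins$role == "syringe", ]
  if (nrow(syr) == 0) stop("phantom has no syringes")

  cx <- img_coords(n, spacing)
  xg <- matrix(cx, n, n); yg <- matrix(cx, n, n, byrow = TRUE)
  support <- map_support(rasterize(spec, n, spacing, supersample = 2))
  ## erode the support edge and carve out every insert with a margin
  rr <- sqrt(xg^2 + yg^2)
  mask <- support
  fov <- dec$fov_mm %||% Inf
  if (is.finite(fov)) mask <- mask & (rr <= fov / 2 - 3 * spacing)
  shell <- spec$layers[1, ]
  mask <- mask & ((xg / (shell$rx - 2 * spacing))^2 +
                    (yg / (shell$ry - 2 * spacing))^2 <= 1)
  for (k in seq_len(nrow(ins))) {
    mask <- mask & ((xg - ins$x[k])^2 + (yg - ins$y[k])^2 >
                      (ins$rx[k] + insert_margin_mm)^2)
  }
  Z <- cbind(1, xg[mask], yg[mask], xg[mask]^2, xg[mask] * yg[mask],
             yg[mask]^2)
  beta <- qr.solve(Z, unclass(img)[mask])
  bg_at <- function(x, y) {
    sum(beta * c(1, x, y, x^2, x * y, y^2))
  }
  vals <- vapply(seq_len(nrow(syr)), function(k) {
    roi_mean(img, syr$x[k], syr$y[k], syr$rx[k] * roi_frac) -
      bg_at(syr$x[k], syr$y[k])
  }, 0)
  list(image = img,
       values = tibble::tibble(conc = syr$conc, value = vals))
}

#' Real-DECT iodine quantification across calibration-phantom sizes
#'
#' Simulates noise-matched 80/140-kVp scans of the calibration phantoms,
#' runs wedge-calibrated projection-domain decomposition, reconstructs the
#' aluminum-basis image, calibrates the origin-constrained conversion factor
#' on the pooled (signal, concentration) samples (unless one is supplied),
#' and reports per-concentration absolute errors averaged over sizes.
#'
#' @param model a [decomp_model()] from the wedge calibration.
#' @param sizes calibration phantom diameters (cm).
#' @param grid reconstruction grid size.
#' @param seed RNG seed (scan seeds are derived from it).
#' @param noise apply Poisson noise.
#' @param calibration optional [calibrate_iodine_factor()] result to reuse.
#' @param slices independent axial slices per phantom; the per-syringe signal
#'   is the mean over slices, mirroring a volumetric ROI over the 5-cm-long
#'   syringes.
#' @return A list: per-syringe `table` (size, conc, value, estimate, error),
#'   `per_conc` size-averaged absolute errors, the `calibration`, and
#'   `max_error` (max over concentrations of the size-averaged error, mg/ml).
#' @export
dect_iodine_experiment <- function(model, sizes = c(18, 23, 28, 33, 38),
                                   grid = 128, seed = 1, noise = TRUE,
                                   calibration = NULL, slices = 4) {
  rows <- list()
  for (i in seq_along(sizes)) {
    spec <- build_calibration_phantom(sizes[i])
    vals <- 0
    for (s in seq_len(slices)) {
      base <- seed + 100 * i + 2 * s
      img_l <- simulate_ct_scan(spec, 80, grid = grid, noise = noise,
                                seed = base)
      img_h <- simulate_ct_scan(spec, 140, grid = grid, noise = noise,
                                seed = base + 1)
      dec <- dect_decompose_images(img_l, img_h, model)
      sig <- aluminum_roi_signals(dec, spec, grid, img_spacing(img_l))
      vals <- vals + sig$values$value / slices
    }
    rows[[i]] <- tibble::tibble(size = sizes[i], conc = sig$values$conc,
                                value = vals)
  }
  tab <- do.call(rbind, rows)
  if (is.null(calibration)) {
    calibration <- calibrate_iodine_factor(
      data.frame(value = tab$value, concentration = tab$conc))
  }
  tab$estimate <- tab$value * calibration$factor
  tab$error <- tab$estimate - tab$conc
  concs <- sort(unique(tab$conc))
  per_conc <- tibble::tibble(
    conc = concs,
    ## |size-averaged estimate - truth|: the study's summary statistic
    ## (signed per-size deviations average out)
    error_of_mean = vapply(concs, function(cc) {
      abs(mean(tab$estimate[tab$conc == cc]) - cc)
    }, 0),
    ## mean over sizes of the per-size absolute error (stricter)
    mean_abs_error = vapply(concs, function(cc) {
      mean(abs(tab$error[tab$conc == cc]))
    }, 0))
  list(table = tab, per_conc = per_conc, calibration = calibration,
       max_error = max(per_conc$error_of_mean),
       max_mean_abs_error = max(per_conc$mean_abs_error))
}

#' Simulate the paired multi-kVp training/testing images
#'
#' @param specs list of [phantom_spec()]s.
#' @param slices independent noise realizations (slices) per phantom.
#' @param grid grid size.
#' @param seed base RNG seed.
#' @param noise apply Poisson noise.
#' @return A list with elements `img_120`, `img_80`, `img_140`, each a list
#'   of images (phantom-major, slice-minor).
#' @export
simulate_paired_scans <- function(specs, slices = 1, grid = 128, seed = 1,
                                  noise = TRUE) {
  out <- list(img_120 = list(), img_80 = list(), img_140 = list())
  k <- 0
  for (spec in specs) {
    for (s in seq_len(slices)) {
      k <- k + 1
      base <- seed + 100 * k
      out$img_120[[k]] <- simulate_ct_scan(spec, 120, grid = grid,
                                           noise = noise, seed = base)
      out$img_80[[k]] <- simulate_ct_scan(spec, 80, grid = grid,
                                          noise = noise, seed = base + 1)
      out$img_140[[k]] <- simulate_ct_scan(spec, 140, grid = grid,
                                           noise = noise, seed = base + 2)
    }
  }
  out
}

#' Pseudo-DECT experiment: train on calibration phantoms, test on Ephan2
#'
#' Trains the energy-mapping CNN on paired 120/80/140-kVp scans of the
#' calibration phantoms, predicts pseudo 80/140-kVp images for a simulated
#' Ephan2, and runs the full in-house pipeline on both real and pseudo DECT:
#' syringe CT numbers, iodine quantification, and masked RMSE/PSNR.
#'
#' @param model wedge-calibrated [decomp_model()].
#' @param calibration [calibrate_iodine_factor()] result from the real-DECT
#'   experiment (the in-house software's conversion factor).
#' @param grid grid size for all scans.
#' @param seed base RNG seed.
#' @param train_sizes calibration phantom sizes used for training.
#' @param slices_per_phantom independent noise realizations per phantom.
#' @param iters SGD iterations.
#' @param channels feature channels of stages 1-2.
#' @param stride training patch stride.
#' @param batch,lr,momentum SGD settings.
#' @param predict_stride sliding-window stride at inference.
#' @param noise apply Poisson noise in the simulations.
#' @return A list: `train` (loss history etc.), `hu_table` (per-syringe real
#'   vs pseudo CT numbers at 80/140 kVp), `iodine_pseudo` and `iodine_real`
#'   per-syringe estimate tables, `metrics` (masked RMSE/PSNR at both
#'   energies), and the predicted images.
#' @export
pseudo_dect_experiment <- function(model, calibration, grid = 128, seed = 1,
                                   train_sizes = c(18, 23, 28, 33, 38),
                                   slices_per_phantom = 3, iters = 1500,
                                   channels = c(16, 8), stride = 14,
                                   batch = 128, lr = 0.01, momentum = 0.9,
                                   predict_stride = 6, noise = TRUE) {
  specs <- lapply(train_sizes, build_calibration_phantom)
  scans <- simulate_paired_scans(specs, slices = slices_per_phantom,
                                 grid = grid, seed = seed, noise = noise)
  patches <- extract_patches(scans$img_120, scans$img_80, scans$img_140,
                             stride = stride)
  net <- build_network(net_config(channels = channels), seed = seed)
  tr <- train_network(net, patches, iters = iters, lr = lr,
                      momentum = momentum, batch = batch, seed = seed + 1)

  spec_e <- build_evaluation_phantom("Ephan2")
  test <- simulate_paired_scans(list(spec_e), slices = 1, grid = grid,
                                seed = seed + 5000, noise = noise)
  img120 <- test$img_120[[1]]; real80 <- test$img_80[[1]]
  real140 <- test$img_140[[1]]
  pred <- predict_full(tr$net, img120, stride = predict_stride)

  syr <- phantom_inserts(spec_e)
  syr <- syr[syr$role == "syringe", ]
  roi_tab <- function(img) {
    vapply(seq_len(nrow(syr)), function(k) {
      roi_mean(img, syr$x[k], syr$y[k], syr$rx[k] * 0.6)
    }, 0)
  }
  hu_table <- tibble::tibble(
    conc = syr$conc,
    real_80 = roi_tab(real80), pseudo_80 = roi_tab(pred$pseudo_80),
    real_140 = roi_tab(real140), pseudo_140 = roi_tab(pred$pseudo_140))
  hu_table$diff_80 <- hu_table$pseudo_80 - hu_table$real_80
  hu_table$diff_140 <- hu_table$pseudo_140 - hu_table$real_140

  iodine_for <- function(img_l, img_h) {
    dec <- dect_decompose_images(img_l, img_h, model)
    sig <- aluminum_roi_signals(dec, spec_e, grid, img_spacing(img_l))
    out <- sig$values
    out$estimate <- out$value * calibration$factor
    out$error <- out$estimate - out$conc
    out
  }
  iodine_real <- iodine_for(real80, real140)
  ## the pseudo 140-kVp image inherits the full field of view of its 120-kVp
  ## source; restrict to the real high-energy FOV for a like-for-like pipeline
  p140 <- pred$pseudo_140
  attr(p140, "fov_mm") <- attr(real140, "fov_mm")
  iodine_pseudo <- iodine_for(pred$pseudo_80, p140)

  sp <- img_spacing(img120)
  support <- map_support(rasterize(spec_e, grid, sp))
  mask <- make_mask(support, attr(real140, "fov_mm") %||% Inf, sp)
  metrics <- rbind(
    cbind(kvp = 80, rmse_psnr(real80, pred$pseudo_80, mask)),
    cbind(kvp = 140, rmse_psnr(real140, p140, mask)))

  list(train = tr, patches_n = dim(patches$input)[4], hu_table = hu_table,
       iodine_pseudo = iodine_pseudo, iodine_real = iodine_real,
       metrics = tibble::as_tibble(metrics),
       images = list(img_120 = img120, real_80 = real80, real_140 = real140,
                     pseudo_80 = pred$pseudo_80, pseudo_140 = p140),
       max_hu_diff_80 = max(abs(hu_table$diff_80)),
       max_iodine_error = max(abs(iodine_pseudo$error)))
}

## ---- resumable workflow ----------------------------------------------------

#' Configuration for [run_workflow()]
#'
#' @param dir output directory for stage artifacts.
#' @param grid grid size; `seed` base seed; `sizes` calibration phantom
#'   sizes; `slices` noise realizations per phantom; `iters`, `channels`,
#'   `stride`, `predict_stride`, `batch` CNN settings; `photons_per_pixel`
#'   wedge photon budget; `vm_energies` virtual monochromatic energies (keV);
#'   `noise` toggles all Poisson noise.
#' @param ... overrides of the quick-profile defaults.
#' @return A named list of workflow settings.
#' @export
workflow_config <- function(dir, grid = 64, seed = 1, sizes = c(18, 28, 38),
                            slices = 1, iters = 25, channels = c(4, 4),
                            stride = 14, predict_stride = 9, batch = 64,
                            photons_per_pixel = 1e5, vm_energies = c(40, 70),
                            noise = TRUE, ...) {
  utils::modifyList(list(dir = dir, grid = grid, seed = seed, sizes = sizes,
                         slices = slices, iters = iters, channels = channels,
                         stride = stride, predict_stride = predict_stride,
                         batch = batch, photons_per_pixel = photons_per_pixel,
                         vm_energies = vm_energies, noise = noise),
                    list(...))
}

workflow_stages <- function() {
  c("wedge_calibrate", "simulate", "train", "predict", "decompose", "vmct",
    "iodine", "evaluate")
}

#' Run the end-to-end pseudo-DECT workflow
#'
#' Executes wedge calibration, scan simulation, CNN training, pseudo-DECT
#' prediction, projection-domain decomposition, VMCT synthesis, iodine
#' quantification and metric evaluation, persisting every stage's artifact
#' under `config$dir`. On re-run, a stage is recomputed only if its artifact
#' is missing or an upstream stage was recomputed, so deleting one
#' intermediate triggers only the downstream part of the pipeline.
#'
#' @param config a [workflow_config()].
#' @return A list: `report` (the metric report), `ran` (names of stages
#'   executed this call), and `artifacts` (paths of the stage files).
#' @export
run_workflow <- function(config) {
  dir.create(config$dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$dir, paste0(workflow_stages(), ".rds"))
  names(paths) <- workflow_stages()
  ran <- character()
  dirty <- FALSE
  stage <- function(name, deps, fn) {
    if (!file.exists(paths[[name]]) || dirty) {
      message("[workflow] running stage: ", name)
      t0 <- proc.time()[3]
      value <- fn(stats::setNames(lapply(deps, function(d) readRDS(paths[[d]])),
                                  deps))
      saveRDS(value, paths[[name]])
      message(sprintf("[workflow] %s done in %.1f s", name,
                      proc.time()[3] - t0))
      ran <<- c(ran, name)
      dirty <<- TRUE
    }
    invisible()
  }
  cfg <- config

  stage("wedge_calibrate", character(), function(deps) {
    wedge_calibration_experiment(cfg$photons_per_pixel, seed = cfg$seed,
                                 noise = cfg$noise)
  })
  stage("simulate", character(), function(deps) {
    specs <- lapply(cfg$sizes, build_calibration_phantom)
    train <- simulate_paired_scans(specs, slices = cfg$slices,
                                   grid = cfg$grid, seed = cfg$seed,
                                   noise = cfg$noise)
    test <- simulate_paired_scans(list(build_evaluation_phantom("Ephan2")),
                                  slices = 1, grid = cfg$grid,
                                  seed = cfg$seed + 5000, noise = cfg$noise)
    list(train = train, test = test)
  })
  stage("train", "simulate", function(deps) {
    sc <- deps$simulate$train
    patches <- extract_patches(sc$img_120, sc$img_80, sc$img_140,
                               stride = cfg$stride)
    net <- build_network(net_config(channels = cfg$channels), seed = cfg$seed)
    train_network(net, patches, iters = cfg$iters, batch = cfg$batch,
                  seed = cfg$seed + 1)
  })
  stage("predict", c("simulate", "train"), function(deps) {
    img120 <- deps$simulate$test$img_120[[1]]
    pred <- predict_full(deps$train$net, img120, stride = cfg$predict_stride)
    attr(pred$pseudo_140, "fov_mm") <-
      attr(deps$simulate$test$img_140[[1]], "fov_mm")
    pred
  })
  stage("decompose", c("wedge_calibrate", "simulate", "predict"), function(deps) {
    model <- deps$wedge_calibrate$model
    test <- deps$simulate$test
    list(real = dect_decompose_images(test$img_80[[1]], test$img_140[[1]],
                                      model),
         pseudo = dect_decompose_images(deps$predict$pseudo_80,
                                        deps$predict$pseudo_140, model))
  })
  stage("vmct", "decompose", function(deps) {
    sp <- 500 / cfg$grid
    lapply(c(real = "real", pseudo = "pseudo"), function(which) {
      dec <- deps$decompose[[which]]
      lapply(cfg$vm_energies, function(e) {
        vm <- synthesize_vm_projection(dec$x_A, dec$x_B, e)
        reconstruct_vmct(vm, cfg$grid, sp, provenance = paste0(which, "-DECT"))
      })
    })
  })
  stage("iodine", c("wedge_calibrate", "simulate", "decompose"), function(deps) {
    model <- deps$wedge_calibrate$model
    cal_exp <- dect_iodine_experiment(model, sizes = cfg$sizes,
                                      grid = cfg$grid, seed = cfg$seed + 7000,
                                      noise = cfg$noise)
    spec_e <- build_evaluation_phantom("Ephan2")
    sp <- 500 / cfg$grid
    one <- function(dec) {
      sig <- aluminum_roi_signals(dec, spec_e, cfg$grid, sp)
      out <- sig$values
      out$estimate <- out$value * cal_exp$calibration$factor
      out$error <- out$estimate - out$conc
      out
    }
    list(calibration = cal_exp, real = one(deps$decompose$real),
         pseudo = one(deps$decompose$pseudo))
  })
  stage("evaluate", c("simulate", "predict", "vmct", "iodine"), function(deps) {
    test <- deps$simulate$test
    sp <- 500 / cfg$grid
    spec_e <- build_evaluation_phantom("Ephan2")
    support <- map_support(rasterize(spec_e, cfg$grid, sp))
    mask <- make_mask(support, attr(test$img_140[[1]], "fov_mm") %||% Inf, sp)
    mets <- rbind(
      cbind(kvp = 80,
            rmse_psnr(test$img_80[[1]], deps$predict$pseudo_80, mask)),
      cbind(kvp = 140,
            rmse_psnr(test$img_140[[1]], deps$predict$pseudo_140, mask)))
    syr <- phantom_inserts(spec_e)
    syr <- syr[syr$role == "syringe", ]
    roi35 <- unlist(syr[which.max(syr$conc), c("x", "y", "rx")])
    cnr_tab <- do.call(rbind, lapply(names(deps$vmct), function(which) {
      tibble::tibble(
        provenance = which, energy_kev = cfg$vm_energies,
        cnr = vapply(deps$vmct[[which]], function(img) {
          cnr(img, c(roi35[1], roi35[2], roi35[3] * 0.6), spec_e$bg_roi[1, ])
        }, 0))
    }))
    report <- list(metrics = tibble::as_tibble(mets), cnr = cnr_tab,
                   iodine_real = deps$iodine$real,
                   iodine_pseudo = deps$iodine$pseudo)
    jsonlite::write_json(
      lapply(report, function(x) if (is.data.frame(x)) x else x),
      file.path(cfg$dir, "metric_report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$metrics, file.path(cfg$dir, "metric_report.csv"),
                     row.names = FALSE)
    report
  })

  list(report = readRDS(paths[["evaluate"]]), ran = ran, artifacts = paths)
}
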