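# NIfTI image I/O, drift-model serialization, run configuration, and the
# end-to-end pipeline tying the stages together.

default_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  a
}

#' Write a series, map, or mask as NIfTI-1
#'
#' 4D series are written as 32-bit float with the voxel size in the header;
#' 3D maps likewise; logical masks/labels as 8-bit integer.
#'
#' @param x a `dwi_series`, 3D/4D numeric array, or logical array
#' @param path output `.nii`/`.nii.gz` path
#' @param voxel_size mm triplet (taken from the series when given one)
#' @return invisibly `path`
#' @export
write_image <- function(x, path, voxel_size = c(2, 2, 4)) {
  if (inherits(x, "dwi_series")) {
    voxel_size <- x$voxel_size
    x <- x$data
  }
  pd <- c(voxel_size, rep(1, max(length(dim(x)) - 3, 0)))
  if (is.logical(x)) {
    x <- array(as.integer(x), dim(x))
    attr(x, "pixdim") <- pd
    img <- RNifti::asNifti(x, datatype = "uint8")
  } else {
    attr(x, "pixdim") <- pd
    img <- RNifti::asNifti(x, datatype = "float")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path input path
#' @param scheme optional `dwi_scheme`; when given, the image must be 4D
#'   with a matching 4th-dimension length, and a `dwi_series` is returned
#' @param mask mask used when constructing a series (defaults to all-TRUE)
#' @param expect_dim optionally require 3 or 4 dimensions
#' @return array (3D/4D), or a `dwi_series` when `scheme` is given
#' @export
read_image <- function(path, scheme = NULL, mask = NULL, expect_dim = NULL) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (!is.null(expect_dim) && length(dim(a)) != expect_dim)
    stop("expected a ", expect_dim, "D image, got ", length(dim(a)), "D")
  vx <- RNifti::pixdim(img)[1:3]
  if (!is.null(scheme)) {
    if (length(dim(a)) != 4)
      stop("a 4D image is required to build a series, got ",
           length(dim(a)), "D")
    if (dim(a)[4] != nrow(scheme))
      stop("4th dimension (", dim(a)[4], ") does not match scheme length (",
           nrow(scheme), ")")
    if (is.null(mask)) mask <- array(TRUE, dim(a)[1:3])
    return(dwi_series(a, scheme, mask, voxel_size = vx))
  }
  attr(a, "voxel_size") <- vx
  a
}

#' Serialize a drift model to JSON
#' @param model a drift model (global or spatiotemporal; voxelwise models
#'   are image-valued and are written as NIfTI coefficient maps instead)
#' @param path output path
#' @return invisibly `path`
#' @export
write_drift_model <- function(model, path) {
  obj <- if (inherits(model, "drift_model_global")) {
    list(type = "global", k = model$k,
         reference_index = model$reference_index)
  } else if (inherits(model, "drift_model_spatiotemporal")) {
    list(type = "spatiotemporal", beta = model$beta, center = model$center,
         scale = model$scale, dim = model$dim,
         reference_index = model$reference_index)
  } else stop("unsupported model type for JSON serialization")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a drift model from JSON
#' @param path path written by [write_drift_model()]
#' @return the drift model
#' @export
read_drift_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    global = new_global_model(obj$k, obj$reference_index),
    spatiotemporal = new_spatiotemporal_model(
      obj$beta, obj$center, obj$scale, obj$dim, obj$reference_index),
    stop("unknown model type: ", obj$type))
}

#' Read and validate a pipeline run configuration
#'
#' YAML (or list) with fields: `protocol` (sivim/diffusive/ballistic),
#' `correction` (none/global/voxelwise/spatiotemporal), `order`
#' (mixed/ordered), `shape` (3 ints), `seed`, `noise_seed`, `snr` (0 =
#' noiseless), `drift` (named targets in %/5 min), `curvature`, `outdir`.
#'
#' @param config a YAML path or a named list
#' @return validated config list with defaults filled in
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(protocol = "diffusive", correction = "spatiotemporal",
                   order = "mixed", shape = c(16, 16, 8), seed = 1L,
                   noise_seed = 2L, snr = 100,
                   drift = list(frontal = -5, inferior = 5),
                   curvature = 0, outdir = tempfile("ivimdrift_run_"))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$protocol %in% c("sivim", "diffusive", "ballistic"),
            cfg$correction %in% c("none", "global", "voxelwise",
                                  "spatiotemporal"),
            cfg$order %in% c("mixed", "ordered"),
            length(cfg$shape) == 3, cfg$snr >= 0)
  cfg$drift <- unlist(cfg$drift)
  cfg
}

fit_drift_method <- function(series, method) {
  switch(method,
    global = fit_global(series),
    voxelwise = fit_voxelwise(series),
    spatiotemporal = fit_spatiotemporal(series))
}

simulate_scan <- function(cfg, phantom, scheme, regime, noise_seed) {
  truth <- forward_signal(phantom, scheme, regime)
  dm <- make_drift_model(phantom, scheme, drift = cfg$drift,
                         curvature = cfg$curvature)
  drifted <- apply_drift(truth, dm)
  if (cfg$snr > 0) {
    sigma <- stats::median(phantom$maps$S0[phantom$mask]) / cfg$snr
    drifted <- add_noise(drifted, sigma, "rician", seed = noise_seed)
  }
  list(series = drifted, model = dm)
}

stage_msg <- function(log, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(...))
  c(log, line)
}

#' Run the full simulation-correction-estimation pipeline
#'
#' Executes simulate -> (optional acquisition-order simulation) -> drift
#' correction -> geometric averaging (and FC/NC normalization for the
#' ballistic protocol) -> IVIM fit -> ROI statistics, writing parameter and
#' residual maps (NIfTI), drift summaries and ROI medians (CSV), the
#' generating drift model (JSON), and a run log into `outdir`. Deterministic
#' given the config seeds.
#'
#' @param config YAML path or list, see [read_run_config()]
#' @return invisibly a list with the output directory, the fit, and the
#'   statistics tables
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- stage_msg(log, "config",
                   sprintf("protocol=%s correction=%s order=%s snr=%g seed=%d",
                           cfg$protocol, cfg$correction, cfg$order, cfg$snr,
                           cfg$seed))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  phantom <- run_stage("simulate", make_phantom(cfg$shape, seed = cfg$seed))
  regime <- switch(cfg$protocol, sivim = "sivim", diffusive = "diffusive",
                   ballistic = "ballistic")
  schemes <- run_stage("simulate", {
    p <- protocol_preset(cfg$protocol)
    if (cfg$protocol == "ballistic") p else list(main = p)
  })
  sims <- run_stage("simulate", {
    lapply(seq_along(schemes), function(i)
      simulate_scan(cfg, phantom, schemes[[i]], regime,
                    noise_seed = cfg$noise_seed + i - 1L))
  })
  names(sims) <- names(schemes)
  log <- stage_msg(log, "simulate", length(sims), " scan(s), shape ",
                   paste(cfg$shape, collapse = "x"))

  if (cfg$order == "ordered") {
    sims <- run_stage("order-sim", lapply(sims, function(s) {
      stm <- fit_spatiotemporal(s$series)
      corr <- apply_correction(s$series, stm)
      s$series <- simulate_ordered(corr, stm)
      s
    }))
    log <- stage_msg(log, "order-sim", "reordered by ascending b-value")
  }

  if (cfg$correction != "none") {
    sims <- run_stage("correct", lapply(sims, function(s) {
      m <- fit_drift_method(s$series, cfg$correction)
      s$series <- apply_correction(s$series, m)
      s$fitted_model <- m
      s
    }))
    log <- stage_msg(log, "correct", "method=", cfg$correction)
  }

  avg <- run_stage("average", {
    if (cfg$protocol == "ballistic") {
      normalize_fc_nc(geometric_average(sims$fc$series),
                      geometric_average(sims$nc$series))
    } else {
      geometric_average(sims[[1]]$series)
    }
  })
  log <- stage_msg(log, "average", length(avg$b), " volumes after averaging")

  fit <- run_stage("fit", switch(regime,
    sivim = fit_sivim(avg),
    diffusive = fit_diffusive(avg),
    ballistic = fit_ballistic(avg)))
  log <- stage_msg(log, "fit", "regime=", regime, ", failed voxels=",
                   if (is.null(fit$details$n_failed)) 0 else
                     fit$details$n_failed)

  res <- residual_map(avg, fit)
  rois <- list(PFWM = roi_mask(phantom, 1), CS = roi_mask(phantom, 2),
               CB = roi_mask(phantom, 3))
  drift_tab <- do.call(rbind, lapply(names(rois), function(rn)
    drift_first_last(sims[[1]]$series, rois[[rn]], roi_label = rn)))
  par_tab <- do.call(rbind, lapply(names(rois), function(rn) {
    vals <- lapply(fit$maps[!vapply(fit$maps, is.null, logical(1))],
                   function(m) stats::median(m[rois[[rn]]], na.rm = TRUE))
    data.frame(roi = rn, parameter = names(vals),
               median = unlist(vals),
               residual_median = stats::median(res[rois[[rn]]], na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  run_stage("write", {
    for (p in names(fit$maps)) {
      if (!is.null(fit$maps[[p]]))
        write_image(fit$maps[[p]], file.path(cfg$outdir,
                                             paste0("map_", p, ".nii.gz")),
                    voxel_size = phantom$voxel_size)
    }
    write_image(res, file.path(cfg$outdir, "residual_rms.nii.gz"),
                voxel_size = phantom$voxel_size)
    write_image(phantom$mask, file.path(cfg$outdir, "mask.nii.gz"),
                voxel_size = phantom$voxel_size)
    write_drift_model(sims[[1]]$model,
                      file.path(cfg$outdir, "drift_model_true.json"))
    utils::write.csv(drift_tab, file.path(cfg$outdir, "drift_roi.csv"),
                     row.names = FALSE)
    utils::write.csv(par_tab, file.path(cfg$outdir, "roi_medians.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(cfg$outdir, "run_log.txt"))
  })

  invisible(list(outdir = cfg$outdir, fit = fit, drift = drift_tab,
                 roi_medians = par_tab, config = cfg))
}
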