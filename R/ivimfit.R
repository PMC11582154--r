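# IVIM parameter estimation: geometric direction-averaging, FC/NC
# normalization, and the three protocol-specific estimators (closed-form
# segmented sIVIM, diffusive biexponential, ballistic with fixed blood
# diffusivity), plus RMS residual maps.

#' Geometric direction-averaging of a series
#'
#' Collapses the volumes to one per unique (b, c, scan label) by the
#' geometric mean over the grouped acquisitions (encoding directions and
#' b = 0 repetitions alike), mitigating background-gradient cross terms.
#' Nonpositive signals are floored to `eps` with a warning before taking
#' logs.
#'
#' @param series a `dwi_series`
#' @param eps floor applied to nonpositive signals
#' @return a `dwi_avg`: list with 4D `data` (one volume per group, sorted by
#'   scan label, b, c), per-volume `b`, `c`, `scan_id`, `n_mean` (mean source
#'   acquisition index), `mask`, `voxel_size`
#' @export
geometric_average <- function(series, eps = 1e-12) {
  sch <- series$scheme
  key <- paste(sch$scan_id, sprintf("%012.4f", sch$b), sprintf("%012.8f", sch$c))
  groups <- split(seq_len(nrow(sch)), key)  # sorted by key: scan, b, c
  shape <- dim(series$mask)
  out <- array(0, c(shape, length(groups)))
  b <- c_val <- n_mean <- numeric(length(groups))
  scan_id <- character(length(groups))
  d <- series$data
  n_floored <- 0L
  for (g in seq_along(groups)) {
    vols <- groups[[g]]
    sub <- d[, , , vols, drop = FALSE]
    bad <- sub <= 0
    if (any(bad & rep(series$mask, length(vols)))) {
      n_floored <- n_floored + sum(bad & rep(series$mask, length(vols)))
    }
    sub[bad] <- eps
    lsum <- apply(log(sub), 1:3, mean)
    out[, , , g] <- exp(lsum)
    b[g] <- sch$b[vols[1]]
    c_val[g] <- sch$c[vols[1]]
    scan_id[g] <- sch$scan_id[vols[1]]
    n_mean[g] <- mean(sch$n[vols])
  }
  if (n_floored > 0)
    warning(n_floored, " nonpositive masked signal(s) floored to ", eps)
  avg <- list(data = out, b = b, c = c_val, scan_id = scan_id,
              n_mean = n_mean, mask = series$mask,
              voxel_size = series$voxel_size)
  class(avg) <- "dwi_avg"
  avg
}

#' Normalize and combine flow-compensated and non-flow-compensated data
#'
#' Each averaged series is divided by the median of its own b = 0 signal
#' inside the mask (removing scaling differences between the two scans), then
#' the two are concatenated into one data set for the joint ballistic fit.
#'
#' @param fc averaged flow-compensated series (c = 0 everywhere)
#' @param nc averaged non-flow-compensated series (c > 0 for b > 0)
#' @param mask optional mask overriding the series masks
#' @return a combined `dwi_avg` (FC volumes first)
#' @export
normalize_fc_nc <- function(fc, nc, mask = NULL) {
  if (is.null(mask)) mask <- fc$mask
  norm1 <- function(avg) {
    ib0 <- which(avg$b == 0)
    if (length(ib0) == 0) stop("series lacks a b = 0 volume")
    med <- stats::median(avg$data[, , , ib0, drop = FALSE][rep(mask, length(ib0))])
    if (med <= 0) stop("nonpositive median b = 0 signal")
    avg$data <- avg$data / med
    avg
  }
  fc <- norm1(fc)
  nc <- norm1(nc)
  comb <- fc
  comb$data <- array(c(fc$data, nc$data),
                     c(dim(mask), length(fc$b) + length(nc$b)))
  comb$b <- c(fc$b, nc$b)
  comb$c <- c(fc$c, nc$c)
  comb$scan_id <- c(fc$scan_id, nc$scan_id)
  comb$n_mean <- c(fc$n_mean, nc$n_mean)
  comb$mask <- mask
  comb
}

new_fit_result <- function(maps, valid, regime, details = list()) {
  r <- list(maps = maps, valid = valid, regime = regime, details = details)
  class(r) <- "ivim_fit"
  r
}

#' Segmented closed-form sIVIM estimation
#'
#' For a three-point protocol (one b = 0 and two nonzero b-values b1 < b2)
#' the monoexponential `S(b) = A exp(-bD)` through the two nonzero points has
#' the closed-form solution `D = (ln S1 - ln S2) / (b2 - b1)` and
#' `A = S1 exp(b1 D)`; the perfusion fraction follows as `f = 1 - A / S0`.
#' `f` is clipped to \[0, 1\] and the clipped fraction recorded; voxels with
#' nonpositive signal at any of the three points are marked invalid.
#'
#' @param avg a `dwi_avg` with exactly two distinct b > 0 volumes and one
#'   b = 0 volume
#' @return an `ivim_fit` with maps `D` (um^2/ms), `f`, `A`, `S0`
#' @export
fit_sivim <- function(avg) {
  bs <- sort(unique(avg$b))
  if (length(bs) != 3 || bs[1] != 0)
    stop("sIVIM requires one b = 0 and exactly two distinct b > 0 volumes")
  i0 <- which(avg$b == bs[1])[1]
  i1 <- which(avg$b == bs[2])[1]
  i2 <- which(avg$b == bs[3])[1]
  shape <- dim(avg$mask)
  S0 <- array(avg$data[, , , i0], shape)
  S1 <- array(avg$data[, , , i1], shape)
  S2 <- array(avg$data[, , , i2], shape)
  valid <- avg$mask & S0 > 0 & S1 > 0 & S2 > 0
  b1 <- b_to_internal(bs[2])
  b2 <- b_to_internal(bs[3])
  D <- (log(S1) - log(S2)) / (b2 - b1)
  A <- S1 * exp(b1 * D)
  f <- 1 - A / S0
  n_clip <- sum((f < 0 | f > 1) & valid)
  f <- pmin(pmax(f, 0), 1)
  D[!valid] <- NA_real_
  A[!valid] <- NA_real_
  f[!valid] <- NA_real_
  S0m <- S0
  S0m[!valid] <- NA_real_
  new_fit_result(ivim_maps(D = D, f = f, S0 = S0m, A = A), valid, "sivim",
                 details = list(b = bs, clipped_f = n_clip,
                                clipped_f_fraction = n_clip / max(sum(valid), 1)))
}

# log-linear monoexponential fit over selected volumes, per voxel vector
segmented_init <- function(y, b, b_min = 200) {
  hi <- which(b >= b_min)
  if (length(hi) < 2) hi <- order(b, decreasing = TRUE)[1:2]
  bh <- b_to_internal(b[hi])
  yh <- pmax(y[hi], 1e-12)
  cf <- stats::lsfit(bh, log(yh))$coefficients
  list(D = -cf[2], A = exp(cf[1]))
}

# per-voxel bounded Levenberg-Marquardt; init_fun may return a matrix of
# candidate starts (one per row), in which case the lowest-deviance fit wins
fit_voxels_nls <- function(avg, par_names, lower, upper, init_fun, model_fun,
                           regime, extra = list()) {
  vox <- which(avg$mask)
  shape <- dim(avg$mask)
  nv <- length(vox)
  est <- matrix(NA_real_, nv, length(par_names))
  ok <- logical(nv)
  npx <- prod(shape)
  nvol <- length(avg$b)
  for (v in seq_len(nv)) {
    y <- avg$data[vox[v] + (seq_len(nvol) - 1L) * npx]
    if (any(!is.finite(y)) || all(y <= 0)) next
    starts <- init_fun(y)
    if (!is.matrix(starts)) starts <- matrix(starts, nrow = 1)
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      p0 <- pmin(pmax(starts[s, ], lower), upper)
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = p0, lower = lower, upper = upper,
          fn = function(p) model_fun(p) - y,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                               ptol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit) || fit$info %in% c(0, 9)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best)) next
    est[v, ] <- best$par
    ok[v] <- TRUE
  }
  maps <- lapply(seq_along(par_names), function(j) {
    a <- array(NA_real_, shape)
    a[vox] <- est[, j]
    a
  })
  names(maps) <- par_names
  valid <- array(FALSE, shape)
  valid[vox] <- ok
  list(maps = maps, valid = valid,
       n_failed = sum(!ok))
}

#' Biexponential IVIM fit, diffusive regime
#'
#' Per-voxel bounded nonlinear least squares of
#' `S(b) = S0((1-f)exp(-bD) + f exp(-bD*))` for (S0, f, D, D*), with a
#' segmented initialization (log-linear monoexponential on b >= 200 s/mm^2
#' for D and the intercept, D* started at 10 um^2/ms). Default bounds:
#' D in \[0.1, 3.5\], D* in \[5, 100\] um^2/ms, f in \[0, 0.5\],
#' S0 in (0, 10 x max signal\]. Voxels that fail to converge are flagged
#' invalid (NA in all maps).
#'
#' @param avg a `dwi_avg` with >= 4 distinct b-values
#' @param bounds optional named list overriding elements of the default
#'   bounds: `D`, `Dstar`, `f`, `S0`, each a (lower, upper) pair
#' @return an `ivim_fit` with maps `D`, `f`, `Dstar`, `S0`
#' @export
fit_diffusive <- function(avg, bounds = list()) {
  if (length(unique(avg$b)) < 4)
    stop("diffusive fit requires >= 4 distinct b-values")
  smax <- max(avg$data)
  bd <- utils::modifyList(
    list(D = c(0.1, 3.5), Dstar = c(5, 100), f = c(0, 0.5),
         S0 = c(1e-12, 10 * smax)), bounds)
  lower <- c(bd$S0[1], bd$f[1], bd$D[1], bd$Dstar[1])
  upper <- c(bd$S0[2], bd$f[2], bd$D[2], bd$Dstar[2])
  b <- avg$b
  bi <- b_to_internal(b)
  i0 <- which(b == 0)
  init_fun <- function(y) {
    sg <- segmented_init(y, b)
    S0o <- if (length(i0)) mean(y[i0]) else max(y)
    f0 <- 1 - sg$A / max(S0o, 1e-12)
    c(S0o, f0, sg$D, 10)
  }
  model_fun <- function(p) p[1] * ((1 - p[2]) * exp(-bi * p[3]) +
                                   p[2] * exp(-bi * p[4]))
  r <- fit_voxels_nls(avg, c("S0", "f", "D", "Dstar"), lower, upper,
                      init_fun, model_fun, "diffusive")
  new_fit_result(ivim_maps(D = r$maps$D, f = r$maps$f, Dstar = r$maps$Dstar,
                           S0 = r$maps$S0),
                 r$valid, "diffusive",
                 details = list(bounds = bd, n_failed = r$n_failed))
}

#' Ballistic IVIM fit with fixed blood diffusivity
#'
#' Per-voxel bounded nonlinear least squares of
#' `S(b, c) = S0((1-f)exp(-bD) + f exp(-b D_b) exp(-c^2 v_d^2))` for
#' (S0, f, D, v_d) with the blood diffusion coefficient `D_b` held fixed
#' (default 1.75 um^2/ms). Requires a combined flow-compensated (c = 0) and
#' non-flow-compensated (c > 0) data set; `v_d` is unidentifiable from c = 0
#' data alone. Initialization is a segmented closed-form estimate on the
#' c = 0 subset. Default bounds: D in \[0.1, 3.5\] um^2/ms, f in \[0, 0.5\],
#' v_d in \[0, 10\] mm/s.
#'
#' @param avg a combined `dwi_avg` (see [normalize_fc_nc()]) with >= 4
#'   distinct (b, c) pairs
#' @param D_b blood diffusion coefficient (um^2/ms), fixed
#' @param bounds optional named list overriding `D`, `f`, `v_d`, `S0` bounds
#' @return an `ivim_fit` with maps `D`, `f`, `v_d`, `S0`
#' @export
fit_ballistic <- function(avg, D_b = 1.75, bounds = list()) {
  if (!any(avg$c > 0))
    stop("v_d is unidentifiable: no c > 0 volumes in the input")
  if (nrow(unique(cbind(avg$b, avg$c))) < 4)
    stop("ballistic fit requires >= 4 distinct (b, c) pairs")
  smax <- max(avg$data)
  bd <- utils::modifyList(
    list(D = c(0.1, 3.5), f = c(0, 0.5), v_d = c(0, 10),
         S0 = c(1e-12, 10 * smax)), bounds)
  lower <- c(bd$S0[1], bd$f[1], bd$D[1], bd$v_d[1])
  upper <- c(bd$S0[2], bd$f[2], bd$D[2], bd$v_d[2])
  b <- avg$b
  cc <- avg$c
  bi <- b_to_internal(b)
  fc_idx <- which(cc == 0)
  # segmented start from the c = 0 subset; the rigid perfusion term
  # (fixed D_b, slow decay over the low-b range) makes the segmented f
  # unreliable, so additional (f, v_d) starts guard against the local
  # minimum at f ~ 0 (where the v_d gradient vanishes) and at the v_d bound
  init_fun <- function(y) {
    yfc <- y[fc_idx]
    bfc <- b[fc_idx]
    sg <- segmented_init(yfc, bfc, b_min = 100)
    i0 <- which(bfc == 0)
    S0o <- if (length(i0)) mean(yfc[i0]) else max(yfc)
    f0 <- max(1 - sg$A / max(S0o, 1e-12), 0.01)
    rbind(c(S0o, f0, sg$D, 1.5),
          c(S0o, 0.03, sg$D, 1),
          c(S0o, 0.03, sg$D, 2.5))
  }
  model_fun <- function(p) p[1] * ((1 - p[2]) * exp(-bi * p[3]) +
                                   p[2] * exp(-bi * D_b) * exp(-cc^2 * p[4]^2))
  r <- fit_voxels_nls(avg, c("S0", "f", "D", "v_d"), lower, upper,
                      init_fun, model_fun, "ballistic")
  new_fit_result(ivim_maps(D = r$maps$D, f = r$maps$f, v_d = r$maps$v_d,
                           S0 = r$maps$S0),
                 r$valid, "ballistic",
                 details = list(bounds = bd, D_b = D_b,
                                n_failed = r$n_failed))
}

#' Predicted signals for a fitted IVIM model
#'
#' @param fit an `ivim_fit`
#' @param b,c_val per-volume b-values (s/mm^2) and flow-encoding factors
#'   (s/mm)
#' @return 4D array of model-predicted signals (NA at invalid voxels)
#' @export
predict_signal <- function(fit, b, c_val = rep(0, length(b))) {
  m <- fit$maps
  shape <- dim(fit$valid)
  out <- array(NA_real_, c(shape, length(b)))
  for (j in seq_along(b)) {
    bi <- b_to_internal(b[j])
    vol <- switch(fit$regime,
      sivim = if (b[j] == 0) m$S0 else m$A * exp(-bi * m$D),
      diffusive = m$S0 * ((1 - m$f) * exp(-bi * m$D) +
                          m$f * exp(-bi * m$Dstar)),
      ballistic = m$S0 * ((1 - m$f) * exp(-bi * m$D) +
                          m$f * exp(-bi * fit$details$D_b) *
                            exp(-c_val[j]^2 * m$v_d^2)))
    vol[!fit$valid] <- NA_real_
    out[, , , j] <- vol
  }
  out
}

#' Root-mean-square residual map of an IVIM fit
#'
#' Per voxel, `sqrt(mean over volumes of (model - data)^2)` between the
#' fitted signal representation and the (averaged) data it was fitted to.
#'
#' @param avg the `dwi_avg` the model was fitted to
#' @param fit the corresponding `ivim_fit`
#' @return 3D map in signal units (NA at invalid voxels)
#' @export
residual_map <- function(avg, fit) {
  pred <- predict_signal(fit, avg$b, avg$c)
  res2 <- (pred - avg$data)^2
  sqrt(apply(res2, 1:3, mean))
}
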