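# Signal-drift estimation and correction. All three methods model the b = 0
# signal as a second-order polynomial in acquisition index n (global and
# voxelwise temporal) or in both n and space (spatiotemporal), estimate the
# coefficients from the interspersed b = 0 volumes, and divide the whole
# series by the evaluated field. Fields are normalized to 1 at a reference
# acquisition so that corrected data keep the scale of that acquisition.

# the 81 spatiotemporal terms n^i * x^a * y^b * z^g, i,a,b,g in {0,1,2};
# row order is fixed (i fastest, then a, b, g) and shared by the fitter,
# the evaluator, and the synthetic drift generator
terms81 <- function() {
  tt <- as.matrix(expand.grid(i = 0:2, a = 0:2, b = 0:2, g = 0:2))
  storage.mode(tt) <- "integer"
  tt
}

# affine map from voxel indices (1-based) to [-1, 1] over the mask bounding
# box, for conditioning of the polynomial design
spatial_normalization <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  scale <- pmax((hi - lo) / 2, 0.5)
  list(center = (lo + hi) / 2, scale = scale)
}

new_global_model <- function(k, reference_index) {
  m <- list(k = k, reference_index = reference_index)
  class(m) <- c("drift_model_global", "drift_model")
  m
}

new_voxelwise_model <- function(k0, k1, k2, mask, reference_index) {
  m <- list(k0 = k0, k1 = k1, k2 = k2, mask = mask,
            reference_index = reference_index)
  class(m) <- c("drift_model_voxelwise", "drift_model")
  m
}

new_spatiotemporal_model <- function(beta, center, scale, dim,
                                     reference_index, iterations = NA_integer_,
                                     converged = NA) {
  stopifnot(length(beta) == 81)
  m <- list(beta = as.numeric(beta), center = center, scale = scale,
            dim = dim, reference_index = reference_index,
            iterations = iterations, converged = converged)
  class(m) <- c("drift_model_spatiotemporal", "drift_model")
  m
}

b0_indices <- function(scheme) scheme$n[scheme$b == 0]

check_b0 <- function(scheme) {
  nb0 <- sum(scheme$b == 0)
  if (nb0 < 3)
    stop("drift fitting requires at least 3 b = 0 acquisitions, found ", nb0)
}

#' Fit the global temporal drift model
#'
#' Ordinary least squares of the per-acquisition median of masked b = 0
#' voxels against acquisition index n:
#' `S(n | b_n = 0) = k0 + k1 n + k2 n^2`.
#'
#' @param series a `dwi_series` with >= 3 b = 0 acquisitions
#' @return a `drift_model_global` with coefficients `k` and the reference
#'   index (first b = 0 acquisition) at which the correction field equals 1
#' @export
fit_global <- function(series) {
  check_b0(series$scheme)
  nb0 <- b0_indices(series$scheme)
  med <- vapply(nb0, function(n)
    stats::median(series$data[, , , n + 1L][series$mask]), numeric(1))
  if (any(med <= 0)) stop("nonpositive b = 0 median signal")
  X <- cbind(1, nb0, nb0^2)
  k <- unname(qr.solve(X, med))
  model <- new_global_model(k, reference_index = nb0[1])
  allfit <- poly_eval(k, series$scheme$n)
  if (any(allfit <= 0))
    stop("fitted global polynomial nonpositive within the scheme")
  model
}

poly_eval <- function(k, n) k[1] + k[2] * n + k[3] * n^2

#' Fit the voxelwise temporal drift model
#'
#' Fits the same second-order polynomial in acquisition index as
#' [fit_global()], but independently in every masked voxel, on the b = 0
#' subset. Voxels where the fitted polynomial turns nonpositive anywhere in
#' the scheme are flagged and removed from the model mask with a warning.
#'
#' @param series a `dwi_series` with >= 3 b = 0 acquisitions
#' @return a `drift_model_voxelwise` with coefficient maps `k0`, `k1`, `k2`
#' @export
fit_voxelwise <- function(series) {
  check_b0(series$scheme)
  nb0 <- b0_indices(series$scheme)
  vox <- which(series$mask)
  shape <- dim(series$mask)
  Y <- vapply(nb0, function(n) series$data[, , , n + 1L][vox],
              numeric(length(vox)))
  X <- cbind(1, nb0, nb0^2)
  coef <- t(qr.solve(X, t(Y)))  # nvox x 3

  fitted_all <- coef %*% rbind(1, series$scheme$n, series$scheme$n^2)
  bad <- apply(fitted_all <= 0, 1, any)
  if (any(bad))
    warning(sum(bad), " voxel(s) with nonpositive fitted drift excluded")
  mask <- array(FALSE, shape)
  mask[vox[!bad]] <- TRUE
  mk <- function(j) {
    a <- array(0, shape)
    a[vox] <- coef[, j]
    a[vox[bad]] <- 0
    a
  }
  new_voxelwise_model(mk(1), mk(2), mk(3), mask,
                      reference_index = nb0[1])
}

# spatial monomial matrix: nvox x 27 columns ordered as (a, b, g) with a
# fastest, matching terms81() within each temporal order
spatial_design <- function(vox_idx, center, scale) {
  xn <- (vox_idx[, 1] - center[1]) / scale[1]
  yn <- (vox_idx[, 2] - center[2]) / scale[2]
  zn <- (vox_idx[, 3] - center[3]) / scale[3]
  sp <- as.matrix(expand.grid(a = 0:2, b = 0:2, g = 0:2))
  M <- matrix(1, nrow(vox_idx), 27)
  for (j in seq_len(27))
    M[, j] <- xn^sp[j, 1] * yn^sp[j, 2] * zn^sp[j, 3]
  M
}

#' Fit the spatiotemporal drift model by Tukey-bisquare regression
#'
#' Normalizes every masked b = 0 volume voxelwise by the first b = 0 volume
#' (removing the anatomical signal distribution), then regresses the
#' normalized values on the 81-term design of all products
#' `n^i * x^a * y^b * z^g` (i, a, b, g in 0..2; x, y, z affinely normalized to
#' \[-1, 1\] over the mask bounding box) using iteratively reweighted least
#' squares with the Tukey biweight loss (tuning constant 4.685, scale
#' 1.4826 x MAD of the residuals re-estimated each iteration).
#'
#' @param series a `dwi_series` with >= 3 b = 0 acquisitions; the number of
#'   masked b = 0 samples must be at least 5 x 81
#' @param max_iter maximum IRLS iterations
#' @param tol relative convergence tolerance on the coefficient vector
#' @param tuning Tukey biweight tuning constant
#' @return a `drift_model_spatiotemporal` (81 coefficients); non-convergence
#'   after `max_iter` iterations is reported with a warning and the last
#'   iterate returned
#' @export
fit_spatiotemporal <- function(series, max_iter = 50L, tol = 1e-8,
                               tuning = 4.685) {
  check_b0(series$scheme)
  if (!any(series$mask)) stop("empty mask")
  nb0 <- b0_indices(series$scheme)
  vox <- which(series$mask)
  vox_idx <- which(series$mask, arr.ind = TRUE)
  n_samples <- length(vox) * length(nb0)
  if (n_samples < 5 * 81)
    stop("too few masked b = 0 samples for 81 coefficients (",
         n_samples, " < ", 5 * 81, ")")

  norm <- spatial_normalization(series$mask)
  Msp <- spatial_design(vox_idx, norm$center, norm$scale)

  ref_vol <- series$data[, , , nb0[1] + 1L][vox]
  if (any(ref_vol <= 0))
    stop("nonpositive signal in the first b = 0 volume inside the mask")

  # stacked design: for each b0 volume, [Msp, n*Msp, n^2*Msp] reordered to
  # the terms81 layout (i fastest within each spatial monomial)
  nrows <- length(vox) * length(nb0)
  X <- matrix(0, nrows, 81)
  y <- numeric(nrows)
  tt <- terms81()
  col_of <- function(i, sp_col) which(tt[, "i"] == i)[sp_col]
  for (k in seq_along(nb0)) {
    rows <- (k - 1L) * length(vox) + seq_along(vox)
    n <- nb0[k]
    for (i in 0:2) {
      cols <- which(tt[, "i"] == i)
      X[rows, cols] <- Msp * n^i
    }
    y[rows] <- series$data[, , , n + 1L][vox] / ref_vol
  }

  qrX <- qr(X)
  if (qrX$rank < 81) stop("singular spatiotemporal design (mask too small?)")
  beta <- qr.coef(qrX, y)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - X %*% beta
    s <- stats::mad(r)
    if (s < 1e-14) { converged <- TRUE; break }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) break
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * as.vector(sw)), y * as.vector(sw))
    delta <- max(abs(beta_new - beta)) / max(abs(beta_new), 1e-12)
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bisquare IRLS did not converge after ", max_iter,
            " iterations; returning last iterate")

  model <- new_spatiotemporal_model(beta, norm$center, norm$scale,
                                    dim(series$mask),
                                    reference_index = nb0[1],
                                    iterations = iter, converged = converged)
  fld <- X %*% beta  # fitted at b0 samples; full check done on evaluation
  if (any(fld <= 0))
    warning("nonpositive fitted drift at some masked b = 0 samples")
  model
}

#' Evaluate a drift model as a normalized 4D correction field
#'
#' `field(n; x,y,z) = fitted(n; x,y,z) / fitted(reference_index; x,y,z)` —
#' dimensionless and equal to 1 at the reference acquisition, so dividing by
#' it preserves the signal scale of that acquisition. Voxels outside the
#' model's mask get field 1 (untouched by correction).
#'
#' @param model a fitted (or constructed) drift model
#' @param scheme the `dwi_scheme` giving the acquisition indices
#' @param dim 3D grid dimensions
#' @return 4D array `dim x length(scheme)`
#' @export
evaluate_field <- function(model, scheme, dim) UseMethod("evaluate_field")

#' @export
evaluate_field.drift_model_global <- function(model, scheme, dim) {
  ref <- poly_eval(model$k, model$reference_index)
  if (ref <= 0) stop("nonpositive fitted value at reference index")
  vals <- poly_eval(model$k, scheme$n) / ref
  if (any(vals <= 0)) stop("nonpositive fitted drift value")
  array(rep(vals, each = prod(dim)), c(dim, nrow(scheme)))
}

#' @export
evaluate_field.drift_model_voxelwise <- function(model, scheme, dim) {
  stopifnot(all(dim(model$mask) == dim))
  vox <- which(model$mask)
  ref <- model$k0[vox] + model$k1[vox] * model$reference_index +
    model$k2[vox] * model$reference_index^2
  if (any(ref <= 0)) stop("nonpositive fitted value at reference index")
  field <- array(1, c(dim, nrow(scheme)))
  npx <- prod(dim)
  for (m in seq_len(nrow(scheme))) {
    n <- scheme$n[m]
    v <- (model$k0[vox] + model$k1[vox] * n + model$k2[vox] * n^2) / ref
    if (any(v <= 0)) stop("nonpositive fitted drift value")
    field[(m - 1L) * npx + vox] <- v
  }
  field
}

#' @export
evaluate_field.drift_model_spatiotemporal <- function(model, scheme, dim) {
  stopifnot(all(model$dim == dim))
  idx <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]),
                               seq_len(dim[3])))
  Msp <- spatial_design(idx, model$center, model$scale)
  tt <- terms81()
  P <- vapply(0:2, function(i) Msp %*% model$beta[tt[, "i"] == i],
              numeric(nrow(Msp)))
  ref <- P[, 1] + P[, 2] * model$reference_index +
    P[, 3] * model$reference_index^2
  field <- array(0, c(dim, nrow(scheme)))
  npx <- prod(dim)
  for (m in seq_len(nrow(scheme))) {
    n <- scheme$n[m]
    field[(m - 1L) * npx + seq_len(npx)] <- (P[, 1] + P[, 2] * n +
                                             P[, 3] * n^2) / ref
  }
  field
}

check_field_positive <- function(field, mask) {
  nvol <- length(field) / length(mask)
  if (any(field[rep(mask, nvol)] <= 0))
    stop("drift field nonpositive inside the mask")
}

#' Correct a series for signal drift
#'
#' Divides every volume (all b-values, not only b = 0) by the evaluated
#' drift field: `S_corr(n) = S(n) / field(n)`.
#'
#' @param series a `dwi_series`
#' @param model a drift model covering the series grid
#' @return the corrected `dwi_series`
#' @export
apply_correction <- function(series, model) {
  field <- evaluate_field(model, series$scheme, dim(series$mask))
  check_field_positive(field, series$mask)
  series$data <- series$data / field
  series
}

#' Re-impose a drift model onto a series
#'
#' Multiplies by the evaluated field — the exact inverse of
#' [apply_correction()] with the same model.
#'
#' @inheritParams apply_correction
#' @return the drifted `dwi_series`
#' @export
apply_inverse <- function(series, model) {
  field <- evaluate_field(model, series$scheme, dim(series$mask))
  check_field_positive(field, series$mask)
  series$data <- series$data * field
  series
}

#' Simulate acquisition in ascending b-value order under the same drift
#'
#' Takes a drift-corrected series and the model used for that correction,
#' permutes the volumes into ascending-b order (directions in canonical
#' succession within each b), and re-imposes the drift with the field
#' evaluated at the new acquisition indices. The result is an uncorrected,
#' b-ordered series as if it had been acquired under the same drift — the
#' drift-sensitive counterpart of the mixed protocol.
#'
#' @param corrected a drift-corrected `dwi_series`
#' @param model the drift model used for the correction (evaluated at the
#'   new indices)
#' @return an uncorrected `dwi_series` with the ordered scheme
#' @export
simulate_ordered <- function(corrected, model) {
  osch <- ordered_scheme(corrected$scheme)
  src <- attr(osch, "source_index")
  out <- corrected
  out$data <- corrected$data[, , , src + 1L, drop = FALSE]
  out$scheme <- osch
  apply_inverse(out, model)
}
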