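test_that("global fit recovers temporal polynomials from b = 0 medians", {
  # constant median M -> (M, 0, 0)
  s <- uniform_series(rep(100, 8))
  g <- fit_global(s)
  expect_equal(unname(g$k), c(100, 0, 0), tolerance = 1e-10)

  # linear decay 100 - 0.5 n recovered exactly by least squares
  vals <- 100 - 0.5 * (0:9)
  g2 <- fit_global(uniform_series(vals))
  expect_equal(unname(g2$k), c(100, -0.5, 0), tolerance = 1e-8)

  # underdetermined with fewer than 3 b = 0 volumes
  s2 <- uniform_series(c(100, 99), b = c(0, 0))
  expect_error(fit_global(s2), "at least 3")
})

test_that("voxelwise fit reduces to the global fit on uniform data and is
           exact on in-family voxels", {
  vals <- 100 * (1 + 0.001 * (0:9))^2  # c (1 + 0.001 n)^2: quadratic in n
  s <- uniform_series(vals)
  vw <- fit_voxelwise(s)
  g <- fit_global(s)
  expect_equal(vw$k0[vw$mask], rep(g$k[1], sum(vw$mask)), tolerance = 1e-8)
  expect_equal(vw$k1[vw$mask], rep(g$k[2], sum(vw$mask)), tolerance = 1e-8)
  expect_equal(vw$k2[vw$mask], rep(g$k[3], sum(vw$mask)), tolerance = 1e-8)
  expect_equal(unname(g$k), 100 * c(1, 2e-3, 1e-6), tolerance = 1e-8)

  # masked-out voxels are untouched by the correction
  s$mask[1, 1, 1] <- FALSE
  vw2 <- fit_voxelwise(s)
  corr <- apply_correction(s, vw2)
  expect_equal(corr$data[1, 1, 1, ], s$data[1, 1, 1, ])
})

test_that("spatiotemporal fit has 81 coefficients and recovers in-family
           fields to high precision", {
  ph <- make_phantom(c(16, 16, 8), seed = 2)
  sch <- protocol_preset("diffusive")
  truth_model <- make_drift_model(ph, sch, drift = c(frontal = -5,
                                                     inferior = 5),
                                  curvature = 0.3, seed = 3)
  truth <- forward_signal(ph, sch, "diffusive")
  drifted <- apply_drift(truth, truth_model)

  fit <- fit_spatiotemporal(drifted)
  expect_length(fit$beta, 81)
  expect_true(fit$converged)

  f_true <- evaluate_field(truth_model, sch, dim(ph$mask))
  f_fit <- evaluate_field(fit, sch, dim(ph$mask))
  inmask <- rep(ph$mask, nrow(sch))
  expect_lt(max(abs(f_fit[inmask] - f_true[inmask]) / f_true[inmask]), 1e-6)

  # small masks are rejected rather than silently overfit
  small <- drifted
  small$mask[] <- FALSE
  small$mask[8:10, 8:10, 4:5] <- TRUE
  expect_error(fit_spatiotemporal(small), "too few")
})

test_that("bisquare regression resists outliers where plain least squares
           does not", {
  ph <- make_phantom(c(16, 16, 8), seed = 9)
  sch <- protocol_preset("diffusive")
  truth_model <- make_drift_model(ph, sch, drift = c(frontal = -5,
                                                     inferior = 5))
  drifted <- apply_drift(forward_signal(ph, sch, "diffusive"), truth_model)

  # corrupt 5% of masked b = 0 voxels in one volume with 10x outliers,
  # keeping the first (reference) b = 0 volume clean
  b0 <- drifted$scheme$n[drifted$scheme$b == 0]
  vox <- which(ph$mask)
  set.seed(31)
  for (n in b0[-1]) {
    hit <- sample(vox, round(0.05 * length(vox)))
    vol <- drifted$data[, , , n + 1]
    vol[hit] <- vol[hit] * 10
    drifted$data[, , , n + 1] <- vol
  }

  f_true <- evaluate_field(truth_model, sch, dim(ph$mask))
  inmask <- rep(ph$mask, nrow(sch))
  rel_err <- function(model) {
    f <- evaluate_field(model, sch, dim(ph$mask))
    max(abs(f[inmask] - f_true[inmask]) / f_true[inmask])
  }
  robust <- fit_spatiotemporal(drifted)
  ols <- suppressWarnings(fit_spatiotemporal(drifted, max_iter = 0L))
  expect_lt(rel_err(robust), 0.005)
  expect_gt(rel_err(ols), 0.005)
})

test_that("evaluated fields are normalized at the reference acquisition and
           flatten their own training data", {
  ph <- make_phantom(c(12, 12, 8), seed = 3)
  sch <- protocol_preset("sivim")
  dm <- make_drift_model(ph, sch, drift = c(frontal = -4, inferior = 3))
  drifted <- apply_drift(forward_signal(ph, sch, "sivim"), dm)

  g <- fit_global(drifted)
  fg <- evaluate_field(g, sch, dim(ph$mask))
  expect_equal(max(abs(fg[, , , g$reference_index + 1] - 1)), 0)
  # global field is spatially constant per volume
  expect_equal(max(apply(fg, 4, function(v) diff(range(v)))), 0)

  # corrected b = 0 median time series is flat for the voxelwise fit
  # (each voxel's drift is exactly quadratic in n here)
  vw <- fit_voxelwise(drifted)
  corr <- apply_correction(drifted, vw)
  b0 <- sch$n[sch$b == 0]
  med <- vapply(b0, function(n) median(corr$data[, , , n + 1][vw$mask]),
                numeric(1))
  slope <- coef(lm(med ~ b0))[2]
  expect_lt(abs(slope) / med[1], 1e-10)
})

test_that("correction and inverse are exact algebraic inverses and commute
           with rescaling", {
  ph <- make_phantom(c(12, 12, 8), seed = 8)
  sch <- protocol_preset("sivim")
  dm <- make_drift_model(ph, sch, drift = c(frontal = -5, inferior = 5))
  s <- forward_signal(ph, sch, "sivim")

  rt <- apply_correction(apply_inverse(s, dm), dm)
  rel <- abs(rt$data - s$data) / pmax(s$data, 1e-300)
  expect_lt(max(rel[rep(ph$mask, nrow(sch))]), 1e-12)

  # drift-free series: fitted then corrected stays put (LSQ recovers
  # constants)
  g <- fit_global(s)
  corr <- apply_correction(s, g)
  rel2 <- abs(corr$data - s$data) / pmax(s$data, 1e-300)
  expect_lt(max(rel2[rep(ph$mask, nrow(sch))]), 1e-8)

  # correction commutes with positive global rescaling
  s2 <- s
  s2$data <- 2.5 * s$data
  expect_equal(apply_correction(s2, dm)$data,
               2.5 * apply_correction(s, dm)$data, tolerance = 1e-12)
})

test_that("fitted corrections remove >= 90% of in-family drift", {
  ph <- make_phantom(c(16, 16, 8), seed = 12)
  sch <- protocol_preset("diffusive")
  dm <- make_drift_model(ph, sch, drift = c(frontal = -5, inferior = 5))
  drifted <- apply_drift(forward_signal(ph, sch, "diffusive"), dm)
  roi <- roi_mask(ph, 1)
  before <- abs(drift_first_last(drifted, roi)$drift_first_last)
  for (method in list(fit_voxelwise, fit_spatiotemporal)) {
    corr <- apply_correction(drifted, method(drifted))
    after <- abs(drift_first_last(corr, roi)$drift_first_last)
    expect_lt(after, 0.1 * before)
  }
})

test_that("simulate_ordered permutes volumes and re-imposes drift at the new
           time points", {
  ph <- make_phantom(c(12, 12, 8), seed = 10)
  sch <- protocol_preset("diffusive")
  s <- forward_signal(ph, sch, "diffusive")

  # identity model: pure reordering
  id <- make_drift_model(ph, sch, drift = c(frontal = 0, inferior = 0))
  os <- simulate_ordered(s, id)
  expect_false(is.unsorted(os$scheme$b))
  expect_equal(sort(os$scheme$b), sort(sch$b))
  src <- attr(os$scheme, "source_index")
  expect_equal(os$data, s$data[, , , src + 1], tolerance = 1e-14)

  # with drift: b = 0 volumes of the output follow the model's trajectory
  dm <- make_drift_model(ph, sch, drift = c(frontal = -5, inferior = 5))
  os2 <- simulate_ordered(s, dm)
  fld <- evaluate_field(dm, os2$scheme, dim(ph$mask))
  expect_equal(os2$data, s$data[, , , src + 1] * fld, tolerance = 1e-12)
})

test_that("ascending-b acquisition under negative frontal drift inflates the
           frontal D estimate", {
  ph <- make_phantom(c(12, 12, 8), seed = 21)
  sch <- protocol_preset("diffusive")
  dm <- make_drift_model(ph, sch, drift = c(frontal = -6, inferior = 6))
  truth <- forward_signal(ph, sch, "diffusive")
  mixed <- apply_drift(truth, dm)         # drift as acquired (mixed order)
  ordered <- simulate_ordered(truth, dm)  # same drift, ascending-b order

  roi <- roi_mask(ph, 1)
  med_D <- function(series) {
    avg <- geometric_average(series)
    avg$mask <- roi
    median(fit_diffusive(avg)$maps$D[roi], na.rm = TRUE)
  }
  expect_gt(med_D(ordered), med_D(mixed))
})
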