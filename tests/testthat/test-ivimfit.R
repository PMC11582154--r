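test_that("geometric averaging is the exact log-domain mean per (b, c) group", {
  shape <- c(2, 2, 2)
  sch <- build_mixed_scheme(c(0, 200, 0, 200), n_cycles = 1)
  data <- array(0, c(shape, 4))
  data[, , , 1] <- 2; data[, , , 3] <- 8    # b = 0 pair: geometric mean 4
  data[, , , 2] <- 5; data[, , , 4] <- 5    # identical repeats -> 5
  s <- dwi_series(data, sch, mask = array(TRUE, shape))
  avg <- geometric_average(s)
  expect_equal(length(avg$b), 2L)
  expect_equal(avg$data[, , , avg$b == 0], array(4, shape))
  expect_equal(avg$data[, , , avg$b == 200], array(5, shape))

  # log of output equals arithmetic mean of logs
  ph <- make_phantom(c(12, 12, 8), seed = 13)
  sp <- protocol_preset("sivim")
  s2 <- forward_signal(ph, sp, "sivim")
  s2 <- add_noise(s2, 5, "rician", seed = 1)
  avg2 <- geometric_average(s2)
  for (g in seq_along(avg2$b)) {
    vols <- which(sp$b == avg2$b[g])
    expect_equal(log(avg2$data[, , , g]),
                 apply(log(s2$data[, , , vols, drop = FALSE]), 1:3, mean),
                 tolerance = 1e-12)
  }
  expect_equal(sort(avg2$b), c(0, 200, 800))
})

test_that("FC/NC normalization removes scale and concatenates volumes", {
  ph <- make_phantom(c(12, 12, 8), seed = 14)
  pb <- protocol_preset("ballistic")
  fc <- geometric_average(forward_signal(ph, pb$fc, "ballistic"))
  nc <- geometric_average(forward_signal(ph, pb$nc, "ballistic"))

  comb <- normalize_fc_nc(fc, fc)  # identical inputs
  half <- length(fc$b)
  expect_equal(comb$data[, , , 1:half], comb$data[, , , half + 1:half])
  expect_equal(median(comb$data[, , , comb$b == 0][rep(ph$mask, 2)]), 1,
               tolerance = 1e-12)

  comb1 <- normalize_fc_nc(fc, nc)
  nc3 <- nc
  nc3$data <- 3 * nc$data
  comb3 <- normalize_fc_nc(fc, nc3)
  expect_equal(comb1$data, comb3$data, tolerance = 1e-12)
  expect_equal(length(comb1$b), length(fc$b) + length(nc$b))
  expect_true(any(comb1$c > 0))
})

test_that("sIVIM closed-form solutions invert the monoexponential exactly", {
  shape <- c(2, 2, 1)
  sch <- build_mixed_scheme(c(0, 200, 800), n_cycles = 2)
  data <- array(0, c(shape, 6))
  for (m in 1:6) {
    data[, , , m] <- switch(as.character(sch$b[m]),
                            "0" = 1.05, "200" = exp(-0.2), "800" = exp(-0.8))
  }
  s <- dwi_series(data, sch, mask = array(TRUE, shape))
  fit <- fit_sivim(geometric_average(s))
  expect_equal(fit$maps$D[1, 1, 1], 1.0, tolerance = 1e-12)
  expect_equal(fit$maps$A[1, 1, 1], 1.0, tolerance = 1e-12)
  expect_equal(fit$maps$f[1, 1, 1], 1 - 1 / 1.05, tolerance = 1e-9)
  expect_equal(fit$maps$f[1, 1, 1], 0.047619, tolerance = 1e-5)

  # f = 0 truth: D recovered to machine precision on the full preset
  truth <- constant_truth_series(protocol_preset("sivim"), "sivim", f = 0,
                                 D = 0.9)
  f0 <- fit_sivim(geometric_average(truth))
  expect_equal(f0$maps$D[1, 1, 1], 0.9, tolerance = 1e-12)

  # noiseless biexponential input: residual pseudo-diffusion signal at
  # b = 200 steepens the apparent (200, 800) decay, so the segmented D is
  # biased up and the segmented f down; both approach truth as Dstar grows
  # (forward-model oracle: closed-form evaluation of Eqs above)
  fh_prev <- -Inf
  for (Dstar in c(10, 15, 30)) {
    tb <- constant_truth_series(protocol_preset("sivim"), "sivim",
                                D = 0.7, f = 0.04, Dstar = Dstar)
    fb <- fit_sivim(geometric_average(tb))
    expect_lte(fb$maps$f[1, 1, 1], 0.04)
    expect_gte(fb$maps$D[1, 1, 1], 0.7)
    expect_gt(fb$maps$f[1, 1, 1], fh_prev)
    fh_prev <- fb$maps$f[1, 1, 1]
  }
})

test_that("diffusive biexponential fit recovers noiseless truth and respects
           bounds", {
  sch <- protocol_preset("diffusive")
  s <- constant_truth_series(sch, "diffusive", D = 0.7, f = 0.05,
                             Dstar = 15, S0 = 1000)
  fit <- fit_diffusive(geometric_average(s))
  expect_equal(fit$maps$D[1, 1, 1], 0.7, tolerance = 1e-3)
  expect_equal(fit$maps$f[1, 1, 1], 0.05, tolerance = 1e-3 * 0.05 / 0.05)
  expect_equal(fit$maps$Dstar[1, 1, 1], 15, tolerance = 15e-3)
  expect_equal(fit$maps$S0[1, 1, 1], 1000, tolerance = 1)

  # f = 0 truth
  s0 <- constant_truth_series(sch, "diffusive", D = 0.8, f = 0)
  f0 <- fit_diffusive(geometric_average(s0))
  expect_equal(f0$maps$D[1, 1, 1], 0.8, tolerance = 8e-4)
  expect_lte(f0$maps$f[1, 1, 1], 0.005)

  # true Dstar below the lower bound is clipped to the bound
  slow <- constant_truth_series(sch, "diffusive", D = 0.7, f = 0.05,
                                Dstar = 3)
  fslow <- fit_diffusive(geometric_average(slow))
  expect_equal(fslow$maps$Dstar[1, 1, 1], 5, tolerance = 1e-6)

  expect_error(fit_diffusive(geometric_average(
    constant_truth_series(build_mixed_scheme(c(0, 200, 800), n_cycles = 2),
                          "diffusive"))), ">= 4")
})

test_that("ballistic fit recovers noiseless truth with fixed blood
           diffusivity", {
  pb <- protocol_preset("ballistic")
  mk <- function(D = 0.8, f = 0.04, v_d = 1.5, S0 = 1000, nc = pb$nc) {
    normalize_fc_nc(
      geometric_average(constant_truth_series(pb$fc, "ballistic", D = D,
                                              f = f, v_d = v_d, S0 = S0)),
      geometric_average(constant_truth_series(nc, "ballistic", D = D,
                                              f = f, v_d = v_d, S0 = S0)))
  }
  fit <- fit_ballistic(mk())
  expect_equal(fit$maps$D[1, 1, 1], 0.8, tolerance = 0.8 * 5e-3)
  expect_equal(fit$maps$f[1, 1, 1], 0.04, tolerance = 0.04 * 5e-3)
  expect_equal(fit$maps$v_d[1, 1, 1], 1.5, tolerance = 1.5 * 5e-3)

  # v_d = 0 truth collapses to the flow-compensated signal everywhere
  f0 <- fit_ballistic(mk(v_d = 0))
  expect_lte(f0$maps$v_d[1, 1, 1], 0.01)

  # doubling the flow-encoding factors of the same signals halves the
  # recovered v_d: only the product c * v_d enters the noiseless signal
  comb <- mk(v_d = 1.5)
  comb$c <- 2 * comb$c
  fit2 <- fit_ballistic(comb)
  expect_equal(fit2$maps$v_d[1, 1, 1], 0.75, tolerance = 0.75 * 5e-3)

  # all-c-zero input leaves v_d unidentifiable
  expect_error(fit_ballistic(normalize_fc_nc(
    geometric_average(constant_truth_series(pb$fc, "ballistic")),
    geometric_average(constant_truth_series(pb$fc, "ballistic")))),
    "unidentifiable")
})

test_that("estimators are invariant to global rescaling of the input", {
  sch <- protocol_preset("diffusive")
  s <- constant_truth_series(sch, "diffusive", D = 0.75, f = 0.04,
                             Dstar = 12, S0 = 800)
  s2 <- s
  s2$data <- 7 * s$data
  f1 <- fit_diffusive(geometric_average(s))
  f2 <- fit_diffusive(geometric_average(s2))
  expect_equal(f2$maps$D[1, 1, 1], f1$maps$D[1, 1, 1], tolerance = 1e-6)
  expect_equal(f2$maps$f[1, 1, 1], f1$maps$f[1, 1, 1], tolerance = 1e-6)
  expect_equal(f2$maps$S0[1, 1, 1], 7 * f1$maps$S0[1, 1, 1],
               tolerance = 1e-6)
})

test_that("residual maps are near zero for self-consistent fits and flag
           drift contamination", {
  sch <- protocol_preset("diffusive")
  s <- constant_truth_series(sch, "diffusive", S0 = 1000)
  avg <- geometric_average(s)
  fit <- fit_diffusive(avg)
  res <- residual_map(avg, fit)
  expect_lt(max(res), 1e-8 * 1000)

  # invariant under volume reordering
  perm <- rev(seq_along(avg$b))
  avg2 <- avg
  avg2$data <- avg$data[, , , perm, drop = FALSE]
  avg2$b <- avg$b[perm]
  avg2$c <- avg$c[perm]
  expect_equal(residual_map(avg2, fit), res, tolerance = 1e-12)

  # drift-contaminated data fit worse than spatiotemporally corrected data
  ph <- make_phantom(c(12, 12, 8), seed = 17)
  schd <- protocol_preset("diffusive")
  dm <- make_drift_model(ph, schd, drift = c(frontal = -8, inferior = 8))
  drifted <- apply_drift(forward_signal(ph, schd, "diffusive"), dm)
  corrected <- apply_correction(drifted, fit_spatiotemporal(drifted))
  roi <- roi_mask(ph, 1)
  res_of <- function(series) {
    avg <- geometric_average(series)
    avg$mask <- roi
    fit <- fit_diffusive(avg)
    median(residual_map(avg, fit)[roi], na.rm = TRUE)
  }
  expect_gt(res_of(drifted), res_of(corrected))
})
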