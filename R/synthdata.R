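# Synthetic brain-like IVIM phantom: piecewise-smooth parameter maps on an
# ellipsoidal "brain", three cubic ROIs at spatial extremes (mimicking
# prefrontal white matter, centrum semiovale, cerebellum), a multiplicative
# spatiotemporal drift field, and Rician noise.

# run code under a fixed RNG seed without touching the caller's RNG state
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct a set of IVIM parameter maps
#'
#' @param D tissue diffusion coefficient map (um^2/ms)
#' @param f perfusion fraction map (0-1)
#' @param Dstar pseudo-diffusion coefficient map (um^2/ms), diffusive regime
#' @param v_d velocity dispersion map (mm/s), ballistic regime
#' @param S0 b = 0 signal map (arbitrary units)
#' @param A optional intercept map (sIVIM intermediate)
#' @return an `ivim_maps` object (list of 3D arrays)
#' @export
ivim_maps <- function(D = NULL, f = NULL, Dstar = NULL, v_d = NULL,
                      S0 = NULL, A = NULL) {
  m <- list(D = D, f = f, Dstar = Dstar, v_d = v_d, S0 = S0, A = A)
  class(m) <- "ivim_maps"
  m
}

#' Construct a 4D diffusion-weighted image series
#'
#' @param data 4D array, 4th dimension matching the scheme length
#' @param scheme the `dwi_scheme` the volumes were acquired with
#' @param mask 3D logical brain mask
#' @param voxel_size mm triplet
#' @return a `dwi_series`
#' @export
dwi_series <- function(data, scheme, mask, voxel_size = c(2, 2, 4)) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != nrow(scheme))
    stop("4th dimension length must equal scheme length")
  if (any(data < 0)) stop("signal data must be nonnegative")
  s <- list(data = data, scheme = scheme, mask = mask,
            voxel_size = voxel_size)
  class(s) <- "dwi_series"
  s
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# separable box smoothing with edge replication; a few passes approximate a
# Gaussian blur well enough for phantom textures
smooth3d <- function(a, passes = 3L) {
  d <- dim(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- d[ax]
      lo <- clamp_idx(seq_len(n) - 1L, n)
      hi <- clamp_idx(seq_len(n) + 1L, n)
      a <- switch(ax,
        (a[lo, , , drop = FALSE] + a + a[hi, , , drop = FALSE]) / 3,
        (a[, lo, , drop = FALSE] + a + a[, hi, , drop = FALSE]) / 3,
        (a[, , lo, drop = FALSE] + a + a[, , hi, drop = FALSE]) / 3)
    }
  }
  a
}

smooth_field <- function(shape, lo, hi, mask) {
  a <- smooth3d(array(stats::rnorm(prod(shape)), dim = shape))
  rng <- range(a[mask])
  if (diff(rng) < .Machine$double.eps) return(array((lo + hi) / 2, shape))
  lo + (a - rng[1]) / diff(rng) * (hi - lo)
}

#' Generate a brain-like IVIM phantom
#'
#' An ellipsoidal mask filled with piecewise-smooth parameter maps in
#' physiological brain ranges (D 0.6-1.0 um^2/ms, f 1-6%, D* 5-30 um^2/ms,
#' v_d 0.5-3 mm/s, S0 500-1500), plus three disjoint cubic ROIs placed at the
#' anterior (label 1, "PFWM"-like), superior-central (label 2, "CS"-like) and
#' posterior-inferior (label 3, "CB"-like) poles. Axes follow RAS: x
#' left-right, y posterior-anterior, z inferior-superior. Deterministic given
#' `seed`.
#'
#' @param shape 3D grid size, each dimension >= 8
#' @param seed integer RNG seed
#' @param voxel_size mm triplet
#' @return a `dwi_phantom`: list with `maps` (`ivim_maps`), `mask` (logical),
#'   `roi_labels` (integer 3D array, 0 outside ROIs), `voxel_size`
#' @export
make_phantom <- function(shape, seed = 1L, voxel_size = c(2, 2, 4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) stop("each dimension must be >= 8")

  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  ix <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  iz <- slice.index(array(0, shape), 3)
  mask <- ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2 <= 1

  maps <- local_seed(seed, {
    ivim_maps(
      D = smooth_field(shape, 0.6, 1.0, mask),
      f = smooth_field(shape, 0.01, 0.06, mask),
      Dstar = smooth_field(shape, 5, 30, mask),
      v_d = smooth_field(shape, 0.5, 3, mask),
      S0 = smooth_field(shape, 500, 1500, mask)
    )
  })

  hw <- max(1L, min(shape) %/% 10L)
  roi_centers <- rbind(
    c(ctr[1], ctr[2] + 0.7 * semi[2], ctr[3]),            # anterior / frontal
    c(ctr[1], ctr[2], ctr[3] + 0.7 * semi[3]),            # superior-central
    c(ctr[1], ctr[2] - 0.6 * semi[2], ctr[3] - 0.5 * semi[3]) # post.-inferior
  )
  roi_labels <- array(0L, shape)
  for (r in 1:3) {
    cc <- round(roi_centers[r, ])
    xs <- clamp_idx((cc[1] - hw):(cc[1] + hw), shape[1])
    ys <- clamp_idx((cc[2] - hw):(cc[2] + hw), shape[2])
    zs <- clamp_idx((cc[3] - hw):(cc[3] + hw), shape[3])
    roi_labels[xs, ys, zs] <- r
  }
  roi_labels[!mask] <- 0L

  ph <- list(maps = maps, mask = mask, roi_labels = roi_labels,
             voxel_size = voxel_size)
  class(ph) <- "dwi_phantom"
  ph
}

#' Logical mask for one phantom ROI
#' @param phantom a `dwi_phantom`
#' @param label ROI label (1 = frontal/PFWM, 2 = central/CS,
#'   3 = posterior-inferior/CB)
#' @return 3D logical array
#' @export
roi_mask <- function(phantom, label) phantom$roi_labels == label

# b in s/mm^2 with D in um^2/ms: bD dimensionless after b * 1e-3
b_to_internal <- function(b) b * 1e-3

#' Forward-model noiseless IVIM signals for a scheme
#'
#' Diffusive (and sIVIM) regime: `S = S0((1-f)exp(-bD) + f exp(-bD*))`.
#' Ballistic regime: `S = S0((1-f)exp(-bD) + f exp(-b D_b) exp(-c^2 v_d^2))`,
#' with `D_b` the (scalar) intrinsic diffusion coefficient of blood. Signals
#' are zero outside the mask; no drift or noise is applied.
#'
#' @param maps an `ivim_maps` (or a `dwi_phantom`, whose mask is then used)
#' @param scheme a `dwi_scheme`
#' @param regime `"sivim"`, `"diffusive"`, or `"ballistic"`
#' @param mask 3D logical; required when `maps` is not a phantom
#' @param D_b blood diffusion coefficient (um^2/ms), ballistic regime only
#' @param voxel_size mm triplet
#' @return a `dwi_series`
#' @export
forward_signal <- function(maps, scheme, regime = c("diffusive", "sivim",
                                                    "ballistic"),
                           mask = NULL, D_b = 1.75, voxel_size = c(2, 2, 4)) {
  regime <- match.arg(regime)
  if (inherits(maps, "dwi_phantom")) {
    mask <- maps$mask
    voxel_size <- maps$voxel_size
    maps <- maps$maps
  }
  if (is.null(mask)) stop("a mask is required")
  if (any(scheme$b < 0)) stop("negative b-value")
  need <- switch(regime,
    sivim = c("S0", "D", "f", "Dstar"),
    diffusive = c("S0", "D", "f", "Dstar"),
    ballistic = c("S0", "D", "f", "v_d"))
  missing <- need[vapply(maps[need], is.null, logical(1))]
  if (length(missing))
    stop("maps lack fields required for regime ", regime, ": ",
         paste(missing, collapse = ", "))

  shape <- dim(maps$S0)
  data <- array(0, c(shape, nrow(scheme)))
  for (m in seq_len(nrow(scheme))) {
    bi <- b_to_internal(scheme$b[m])
    vol <- if (regime == "ballistic") {
      ci <- scheme$c[m]
      maps$S0 * ((1 - maps$f) * exp(-bi * maps$D) +
                 maps$f * exp(-bi * D_b) * exp(-ci^2 * maps$v_d^2))
    } else {
      maps$S0 * ((1 - maps$f) * exp(-bi * maps$D) +
                 maps$f * exp(-bi * maps$Dstar))
    }
    vol[!mask] <- 0
    data[, , , m] <- vol
  }
  dwi_series(data, scheme, mask, voxel_size)
}

roi_centroid <- function(phantom, label) {
  idx <- which(phantom$roi_labels == label, arr.ind = TRUE)
  colMeans(idx)
}

pole_label <- function(name) {
  switch(tolower(name),
    frontal = , anterior = , pfwm = 1L,
    central = , superior = , cs = 2L,
    inferior = , posterior = , cerebellar = , cb = 3L,
    stop("unknown pole name: ", name)
  )
}

#' Construct a known spatiotemporal drift model
#'
#' Builds a multiplicative drift field in the exact second-order
#' space-and-time polynomial family used by the spatiotemporal correction:
#' `field(n; x,y,z) = 1 + R(x,y,z)/100 * (t_last/300) * ((1-k) tau + k tau^2)`
#' with `tau = t_n / t_last` and `k` the temporal curvature fraction. The
#' spatial rate `R` (in % per 5 min, measured over the full scan) is affine,
#' interpolating the requested target rates at the named pole positions (the
#' centroids of the phantom ROIs). The field is exactly 1 at n = 0 for every
#' voxel, and the end-of-scan drift normalized per 5 min equals the target at
#' each pole. With a `seed`, a small random second-order spatial wobble that
#' vanishes at both poles is added.
#'
#' @param phantom a `dwi_phantom` (supplies grid, mask and pole positions)
#' @param scheme a `dwi_scheme` (supplies the time axis)
#' @param drift named numeric of target drift rates in % per 5 min at one or
#'   two poles, e.g. `c(frontal = -5, inferior = 5)`; magnitudes <= 20
#' @param curvature temporal curvature fraction `k` in `[0, 1]`; 0 gives a
#'   purely linear-in-time drift
#' @param seed optional seed for the spatial wobble term
#' @return a `drift_model_spatiotemporal` (81 coefficients)
#' @export
make_drift_model <- function(phantom, scheme, drift = c(frontal = -5,
                                                        inferior = 5),
                             curvature = 0.3, seed = NULL) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  if (length(drift) < 1 || length(drift) > 2)
    stop("drift must name one or two poles")
  if (any(abs(drift) > 20)) stop("drift magnitudes must be within 20 %/5min")
  if (curvature < 0 || curvature > 1) stop("curvature must be in [0, 1]")
  labels <- vapply(names(drift), pole_label, integer(1))
  if (anyDuplicated(labels))
    stop("inconsistent pole constraints: pole named twice")

  shape <- dim(phantom$mask)
  norm <- spatial_normalization(phantom$mask)
  n_last <- nrow(scheme) - 1L
  t_last <- scheme$t[nrow(scheme)]
  if (t_last <= 0) stop("scheme has zero duration")

  # coefficient vector over the 81 terms n^i * x^a * y^b * z^g (see terms81)
  beta <- numeric(81)
  terms <- terms81()
  beta[terms[, "i"] == 0 & rowSums(terms[, c("a", "b", "g")]) == 0] <- 1

  if (any(drift != 0)) {
    # spatial rate R(p) in normalized coordinates (fraction per full scan)
    pn <- lapply(labels, function(l)
      (roi_centroid(phantom, l) - norm$center) / norm$scale)
    if (length(drift) == 1) {
      r_const <- drift[[1]] / 100
      r_lin <- c(0, 0, 0)
    } else {
      u <- pn[[2]] - pn[[1]]
      uu <- sum(u^2)
      if (uu < .Machine$double.eps)
        stop("inconsistent pole constraints: poles coincide")
      g <- (drift[[2]] - drift[[1]]) / 100 / uu
      r_lin <- g * u
      r_const <- drift[[1]] / 100 - sum(r_lin * pn[[1]])
    }
    rate <- c(r_const, r_lin)  # 1, x, y, z coefficients of R (fraction)

    if (!is.null(seed) && length(drift) == 2) {
      # random second-order wobble q(p), projected so q(pole1) = q(pole2) = 0
      wob <- local_seed(seed,
        stats::rnorm(9, sd = 0.1 * max(abs(drift)) / 100))
      qeval <- function(p) {
        mono <- c(p[1], p[2], p[3], p[1]^2, p[2]^2, p[3]^2,
                  p[1] * p[2], p[1] * p[3], p[2] * p[3])
        sum(wob * mono)
      }
      u <- pn[[2]] - pn[[1]]
      uu <- sum(u^2)
      q1 <- qeval(pn[[1]])
      q2 <- qeval(pn[[2]])
      # s(p) affine with s(p1)=0, s(p2)=1; subtract (1-s) q1 + s q2
      s_lin <- u / uu
      s_const <- -sum(s_lin * pn[[1]])
      rate[1] <- rate[1] - q1 - (q2 - q1) * s_const
      rate[2:4] <- rate[2:4] - (q2 - q1) * s_lin
    } else {
      wob <- NULL
    }

    scale_t <- t_last / 300
    env <- c((1 - curvature) / n_last,            # coefficient of n
             curvature / n_last^2)                # coefficient of n^2
    add_rate_terms <- function(beta, rate_vec) {
      spat <- list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
      for (k in 1:4) {
        for (it in 1:2) {
          j <- which(terms[, "i"] == it &
                     terms[, "a"] == spat[[k]][1] &
                     terms[, "b"] == spat[[k]][2] &
                     terms[, "g"] == spat[[k]][3])
          beta[j] <- beta[j] + rate_vec[k] * scale_t * env[it]
        }
      }
      beta
    }
    beta <- add_rate_terms(beta, rate)
    if (!is.null(wob)) {
      # quadratic part of the wobble (linear part already folded into rate)
      quad <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
      for (k in 1:6) {
        for (it in 1:2) {
          j <- which(terms[, "i"] == it &
                     terms[, "a"] == quad[k, 1] &
                     terms[, "b"] == quad[k, 2] &
                     terms[, "g"] == quad[k, 3])
          beta[j] <- beta[j] + wob[3 + k] * scale_t * env[it]
        }
      }
    }
  }

  model <- new_spatiotemporal_model(beta, norm$center, norm$scale, shape,
                                    reference_index = 0L)
  fld <- evaluate_field(model, scheme, shape)
  if (any(fld[rep(phantom$mask, nrow(scheme))] <= 0))
    stop("unreachable drift spec: field nonpositive inside mask")
  model
}

#' Apply a multiplicative drift field to a series
#'
#' `output(n; x,y,z) = input(n; x,y,z) * field(n; x,y,z)` — the algebraic
#' inverse of [apply_correction()], used to superimpose a known drift on
#' noiseless data (and to re-impose drift after reordering in the
#' acquisition-order simulation).
#'
#' @param series a `dwi_series`
#' @param model a drift model defined over the series grid
#' @return the drifted `dwi_series`
#' @export
apply_drift <- function(series, model) {
  apply_inverse(series, model)
}

#' Add Rician or Gaussian noise to a series
#'
#' Rician: `sqrt((S + e1)^2 + e2^2)` with `e1, e2` independent zero-mean
#' Gaussians of standard deviation `sigma` (magnitude MRI). Gaussian:
#' `S + e1`, clipped at 0. Deterministic given `seed`.
#'
#' @param series a `dwi_series`
#' @param sigma noise standard deviation (signal units); specify e.g. as
#'   `median(S0)/SNR`
#' @param model `"rician"` or `"gaussian"`
#' @param seed integer RNG seed
#' @return a noisy `dwi_series`
#' @export
add_noise <- function(series, sigma, model = c("rician", "gaussian"),
                      seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(series)
  d <- series$data
  noisy <- local_seed(seed, {
    e1 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
    if (model == "rician") {
      e2 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
      sqrt((d + e1)^2 + e2^2)
    } else {
      pmax(d + e1, 0)
    }
  })
  series$data <- noisy
  series
}
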