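# Shared fixtures: all built in code at test time.

# series whose every voxel follows the same temporal profile `values`
uniform_series <- function(values, b = rep(0, length(values)),
                           shape = c(4, 4, 2), volume_interval = 7.5) {
  sch <- build_mixed_scheme(b, n_cycles = 1L,
                            volume_interval = volume_interval)
  data <- array(rep(values, each = prod(shape)), c(shape, length(values)))
  dwi_series(data, sch, mask = array(TRUE, shape))
}

# series of constant IVIM truth on a tiny grid, for estimator round trips
constant_truth_series <- function(scheme, regime, D = 0.7, f = 0.05,
                                  Dstar = 15, v_d = 1.5, S0 = 1000,
                                  shape = c(2, 2, 1)) {
  const <- function(v) array(v, shape)
  maps <- ivim_maps(D = const(D), f = const(f), Dstar = const(Dstar),
                    v_d = const(v_d), S0 = const(S0))
  forward_signal(maps, scheme, regime, mask = array(TRUE, shape))
}

# brute-force Friedman oracle: full enumeration with independent code
friedman_brute <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  R <- t(apply(values, 1, rank))
  stat_of <- function(Rm) {
    12 / (n * k * (k + 1)) * sum(colSums(Rm)^2) - 3 * n * (k + 1)
  }
  obs <- stat_of(R)
  perms <- gtools_permutations(k)
  combos <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  cnt <- 0L
  for (r in seq_len(nrow(combos))) {
    Rm <- t(vapply(seq_len(n), function(b) R[b, perms[combos[r, b], ]],
                   numeric(k)))
    if (stat_of(Rm) >= obs - 1e-9) cnt <- cnt + 1L
  }
  list(statistic = obs, p = cnt / nrow(combos))
}

# minimal permutation generator (independent of the package's internal one)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  out <- NULL
  for (first in seq_len(k)) {
    rest <- gtools_permutations(k - 1L)
    remaining <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(remaining[rest], nrow(rest))))
  }
  unname(out)
}

# brute-force signed-rank oracle: enumerate all 2^n sign assignments
signed_rank_brute <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  cnt <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    Wm <- sum(r[signs == 1])
    if (abs(Wm - mu) >= abs(W - mu) - 1e-9) cnt <- cnt + 1L
  }
  list(statistic = W, p = cnt / 2^n)
}
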