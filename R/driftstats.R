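# ROI-level drift metrics, test-retest repeatability summaries, and the
# exact nonparametric tests (permutation Friedman, Wilcoxon signed-rank)
# used to compare correction methods and acquisition orders.

#' First-to-last b = 0 drift of an ROI, in % per 5 min
#'
#' `100 * (median_roi(S at last b=0) / median_roi(S at first b=0) - 1)`
#' normalized to the elapsed time between the two acquisitions and expressed
#' per 5 minutes (x 300 s / elapsed).
#'
#' @param series a `dwi_series` with >= 2 b = 0 acquisitions
#' @param roi 3D logical ROI mask
#' @param roi_label label stored in the output
#' @return a one-row data.frame: `roi`, `drift_first_last` (%/5 min),
#'   `scan_id`, `b`
#' @export
drift_first_last <- function(series, roi, roi_label = "roi") {
  sch <- series$scheme
  ib0 <- which(sch$b == 0)
  if (length(ib0) < 2) stop("need >= 2 b = 0 acquisitions")
  first <- ib0[1]
  last <- ib0[length(ib0)]
  m_first <- stats::median(series$data[, , , first][roi])
  m_last <- stats::median(series$data[, , , last][roi])
  if (m_first <= 0) stop("nonpositive ROI median at first b = 0 acquisition")
  elapsed <- sch$t[last] - sch$t[first]
  if (elapsed <= 0) stop("zero elapsed time between first and last b = 0")
  drift <- 100 * (m_last / m_first - 1) * 300 / elapsed
  data.frame(roi = roi_label, drift_first_last = drift,
             scan_id = sch$scan_id[1], b = 0, stringsAsFactors = FALSE)
}

#' Slope-based ROI drift at a given b-value, in % per 5 min
#'
#' Least-squares fit of the ROI-median signal against acquisition time with
#' a common slope and one intercept per encoding direction (fixed
#' per-direction intercepts absorbing the directional signal dependence; for
#' b = 0 there is a single intercept). The slope is returned as a percentage
#' of the mean intercept per 5 minutes.
#'
#' @param series a `dwi_series`
#' @param roi 3D logical ROI mask
#' @param b the b-value (s/mm^2) whose volumes enter the fit
#' @param roi_label label stored in the output
#' @return a one-row data.frame: `roi`, `drift_slope` (%/5 min), `scan_id`,
#'   `b`
#' @export
drift_slope <- function(series, roi, b = 0, roi_label = "roi") {
  sch <- series$scheme
  sel <- which(abs(sch$b - b) < 1e-9)
  if (length(sel) < 2) stop("need >= 2 acquisitions at b = ", b)
  y <- vapply(sel, function(m) stats::median(series$data[, , , m][roi]),
              numeric(1))
  t <- sch$t[sel]
  if (b > 0) {
    dr <- direction_rank(series$scheme)[sel]
    grp <- factor(dr)
    if (any(table(grp) < 2))
      stop("need >= 2 time points per encoding direction at b > 0")
    X <- cbind(stats::model.matrix(~ grp - 1), t)
  } else {
    X <- cbind(1, t)
  }
  cf <- qr.solve(X, y)
  slope <- cf[length(cf)]
  intercepts <- cf[-length(cf)]
  drift <- 100 * slope * 300 / mean(intercepts)
  data.frame(roi = roi_label, drift_slope = drift,
             scan_id = sch$scan_id[1], b = b, stringsAsFactors = FALSE)
}

#' Test-retest repeatability of IVIM parameter maps
#'
#' Per ROI and parameter: the average of the two repetitions' ROI medians and
#' the absolute difference between them, the two quantities reported in
#' test-retest tables. Invalid voxels (NA) are excluded.
#'
#' @param maps_rep1,maps_rep2 `ivim_maps` from two repeated scans on the
#'   same grid
#' @param rois named list of 3D logical ROI masks
#' @param parameters which maps to summarize (defaults to all non-null maps
#'   present in both repetitions)
#' @param group optional grouping label (correction method / acquisition
#'   order) copied to every row
#' @return data.frame with columns `parameter`, `roi`, `average`, `abs_diff`
#'   (and `group` if given)
#' @export
repeatability <- function(maps_rep1, maps_rep2, rois, parameters = NULL,
                          group = NULL) {
  if (is.null(parameters)) {
    parameters <- intersect(
      names(maps_rep1)[!vapply(maps_rep1, is.null, logical(1))],
      names(maps_rep2)[!vapply(maps_rep2, is.null, logical(1))])
  }
  rows <- list()
  for (p in parameters) {
    for (rn in names(rois)) {
      v1 <- maps_rep1[[p]][rois[[rn]]]
      v2 <- maps_rep2[[p]][rois[[rn]]]
      v1 <- v1[is.finite(v1)]
      v2 <- v2[is.finite(v2)]
      if (length(v1) == 0 || length(v2) == 0)
        stop("empty ROI '", rn, "' after validity masking")
      m1 <- stats::median(v1)
      m2 <- stats::median(v2)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, roi = rn, average = (m1 + m2) / 2,
        abs_diff = abs(m1 - m2), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(group)) out$group <- group
  out
}

friedman_statistic <- function(R, n, k) {
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

# exact permutation p by convolution over blocks for k <= 3: dynamic
# programming on the (doubled, hence integer) column rank sums of the first
# k - 1 treatments; equivalent to full enumeration of the (k!)^n assignments
# but polynomial in n
friedman_exact_dp <- function(R, n, k, stat_obs) {
  R2 <- round(2 * R)
  M <- 2L * k * n  # largest possible doubled column sum
  perms <- all_permutations(k)
  np <- nrow(perms)
  if (k == 2) {
    dp <- numeric(M + 1)
    dp[1] <- 1
    for (b in seq_len(n)) {
      new <- numeric(M + 1)
      for (p in seq_len(np)) {
        a <- R2[b, perms[p, 1]]
        new[(a + 1):(M + 1)] <- new[(a + 1):(M + 1)] +
          dp[seq_len(M + 1 - a)] / np
      }
      dp <- new
    }
    states <- which(dp > 0) - 1L
    s1 <- states / 2
    s2 <- sum(R2) / 2 - s1
    probs <- dp[states + 1L]
    stats_all <- 12 / (n * k * (k + 1)) * (s1^2 + s2^2) - 3 * n * (k + 1)
  } else {
    dp <- matrix(0, M + 1, M + 1)
    dp[1, 1] <- 1
    for (b in seq_len(n)) {
      new <- matrix(0, M + 1, M + 1)
      for (p in seq_len(np)) {
        a <- R2[b, perms[p, 1]]
        d <- R2[b, perms[p, 2]]
        new[(a + 1):(M + 1), (d + 1):(M + 1)] <-
          new[(a + 1):(M + 1), (d + 1):(M + 1)] +
          dp[seq_len(M + 1 - a), seq_len(M + 1 - d)] / np
      }
      dp <- new
    }
    states <- which(dp > 0, arr.ind = TRUE) - 1L
    s1 <- states[, 1] / 2
    s2 <- states[, 2] / 2
    s3 <- sum(R2) / 2 - s1 - s2
    probs <- dp[states + 1L]
    stats_all <- 12 / (n * k * (k + 1)) * (s1^2 + s2^2 + s3^2) -
      3 * n * (k + 1)
  }
  sum(probs[stats_all >= stat_obs - 1e-9])
}

#' Exact-permutation Friedman test
#'
#' Friedman rank statistic for `n` blocks x `k` related treatments, with
#' average ranks for ties:
#' `chi2_F = 12 / (n k (k+1)) * sum_j R_j^2 - 3 n (k+1)`.
#' The exact p-value is the fraction of all `(k!)^n` equally likely
#' within-block rank permutations whose statistic is at least the observed
#' one. For k <= 3 the permutation distribution is computed exactly by
#' convolution over blocks (identical to full enumeration, but polynomial in
#' n); for larger k the assignments are enumerated directly, and if `(k!)^n`
#' exceeds `enum_cap` and `fallback` is TRUE, the chi-square approximation
#' (df = k - 1) is used instead and noted in the method label.
#'
#' @param values numeric matrix, `n` blocks (rows) x `k` treatments (columns)
#' @param enum_cap largest number of permutations enumerated directly
#' @param fallback use the chi-square approximation above the cap
#' @return list with `statistic`, `p_exact`, `n_blocks`, `k_treatments`,
#'   `method`
#' @export
friedman_exact <- function(values, enum_cap = 1e7, fallback = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2 || k < 2) stop("need n >= 2 blocks and k >= 2 treatments")
  R <- t(apply(values, 1, rank))
  stat <- friedman_statistic(R, n, k)
  if (k <= 3) {
    p <- friedman_exact_dp(R, n, k, stat)
    return(list(statistic = stat, p_exact = p, n_blocks = n,
                k_treatments = k, method = "friedman exact permutation"))
  }
  n_perm <- factorial(k)^n
  if (n_perm > enum_cap) {
    if (!fallback)
      stop("(k!)^n = ", n_perm, " exceeds enumeration cap ", enum_cap)
    message("friedman_exact: enumeration cap exceeded, ",
            "using chi-square approximation")
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    return(list(statistic = stat, p_exact = p, n_blocks = n,
                k_treatments = k, method = "friedman chi-square approx"))
  }
  perms <- all_permutations(k)
  # accumulate column-sum matrices over the product space block by block
  S <- matrix(0, 1, k)
  for (b in seq_len(n)) {
    Pb <- matrix(R[b, ][t(perms)], ncol = k, byrow = TRUE)
    m <- nrow(S)
    S <- S[rep(seq_len(m), each = nrow(Pb)), , drop = FALSE] +
      Pb[rep(seq_len(nrow(Pb)), times = m), , drop = FALSE]
  }
  stats_all <- 12 / (n * k * (k + 1)) * rowSums(S^2) - 3 * n * (k + 1)
  p <- mean(stats_all >= stat - 1e-9)
  list(statistic = stat, p_exact = p, n_blocks = n, k_treatments = k,
       method = "friedman exact permutation")
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Ranks the absolute paired differences (average ranks on ties, zero
#' differences dropped) and computes the positive-rank sum W. The two-sided
#' exact p-value is the probability, over all `2^n` equally likely sign
#' assignments, of a rank sum at least as far from its null mean
#' `n(n+1)/4` as the observed one; computed by dynamic programming over the
#' sign-flip distribution (identical to full enumeration). For `n > n_exact`
#' a normal approximation with tie correction is used.
#'
#' @param x,y paired samples
#' @param n_exact largest n for which the exact distribution is computed
#' @return list with `statistic` (W), `p_exact`, `n_pairs`, `method`
#' @export
signed_rank_exact <- function(x, y, n_exact = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= n_exact) {
    # distribution of W over sign flips: DP on doubled ranks (integers)
    r2 <- round(2 * r)
    tot <- sum(r2)
    dp <- numeric(tot + 1)
    dp[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dp[seq_len(tot + 1 - ri)])
      dp <- dp + shifted
    }
    w_vals <- (0:tot) / 2
    extreme <- abs(w_vals - mu) >= abs(W - mu) - 1e-9
    p <- sum(dp[extreme]) / 2^n
    method <- "wilcoxon signed-rank exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon signed-rank normal approx"
  }
  list(statistic = W, p_exact = p, n_pairs = n, method = method)
}

#' Select the most typical subject/repetition from a drift table
#'
#' For every (roi, scan) column of the drift table, observations are ranked
#' by their absolute distance from that column's median drift (average ranks
#' on ties); the ranks are summed per (subject, repetition) and the pair with
#' the lowest sum — the one closest to typical drift behavior overall — is
#' returned. Ties break toward the lowest subject, then repetition.
#'
#' @param drift_table data.frame with columns `subject`, `repetition`,
#'   `roi`, `scan`, `drift`
#' @return list with `subject`, `repetition`, and the full `rank_sums` table
#' @export
select_representative <- function(drift_table) {
  if (nrow(drift_table) == 0) stop("empty drift table")
  dt <- drift_table
  dt$rank <- stats::ave(
    dt$drift, dt$roi, dt$scan,
    FUN = function(v) rank(abs(v - stats::median(v))))
  sums <- stats::aggregate(rank ~ subject + repetition, data = dt, FUN = sum)
  sums <- sums[order(sums$rank, sums$subject, sums$repetition), ]
  list(subject = sums$subject[1], repetition = sums$repetition[1],
       rank_sums = sums)
}
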