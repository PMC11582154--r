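# Acquisition schemes: ordered tables of (b, direction, c, t, scan_id) with a
# fixed per-volume interval. A scheme is a data.frame of class "dwi_scheme"
# with attributes volume_interval (s) and scan_id.

CANONICAL_DIRECTIONS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1)
)

new_scheme <- function(b, dir, c_val, scan_id, volume_interval) {
  n <- seq_along(b) - 1L
  sch <- data.frame(
    n = n,
    b = as.numeric(b),
    dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
    c = as.numeric(c_val),
    t = n * volume_interval,
    scan_id = scan_id,
    stringsAsFactors = FALSE
  )
  attr(sch, "volume_interval") <- volume_interval
  class(sch) <- c("dwi_scheme", "data.frame")
  sch
}

#' Number of acquisitions in a scheme
#' @param scheme a `dwi_scheme`
#' @return integer count
#' @export
n_acquisitions <- function(scheme) nrow(scheme)

#' Total scheme duration in seconds
#' @param scheme a `dwi_scheme`
#' @return duration = volume interval times number of acquisitions
#' @export
scheme_duration <- function(scheme) {
  attr(scheme, "volume_interval") * nrow(scheme)
}

#' Validate an acquisition scheme
#'
#' Checks the structural invariants every scheme must satisfy: consecutive
#' 0-based indices, nonnegative b and c, unit-norm directions wherever b > 0
#' (b = 0 rows carry the null direction, encoded as all-zero), nondecreasing
#' acquisition times, and at least two b = 0 acquisitions (required by all
#' drift corrections).
#'
#' @param scheme a `dwi_scheme`
#' @return invisibly `TRUE`; errors describe the first violated invariant
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  if (!identical(scheme$n, seq_len(nrow(scheme)) - 1L))
    stop("scheme indices n must be consecutive from 0")
  if (any(scheme$b < 0)) stop("negative b-value in scheme")
  if (any(scheme$c < 0)) stop("negative flow-encoding factor in scheme")
  nrm <- sqrt(scheme$dx^2 + scheme$dy^2 + scheme$dz^2)
  dw <- scheme$b > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("non-unit encoding direction at b > 0")
  if (is.unsorted(scheme$t)) stop("acquisition times must be nondecreasing")
  if (sum(scheme$b == 0) < 2)
    stop("scheme must contain at least two b = 0 acquisitions")
  invisible(TRUE)
}

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a %/% gcd(a, b) * b
}

#' Build a drift-robust ("mixed") acquisition scheme
#'
#' Loops through all combinations of b-values and encoding directions with
#' simultaneous increments of both indices, so that acquisitions with the same
#' b-value but different directions are distributed over the whole scan. At
#' 0-based step `t`, the b index is `t mod B` and the direction index is
#' `(t + floor(t / lcm(B, K))) mod K` for `B = length(b_sequence)` and
#' `K = nrow(directions)`; the extra offset per completed lcm cycle guarantees
#' that every (b, direction) pair is eventually covered. b = 0 entries carry a
#' null direction (repetitions) but still consume a direction slot.
#'
#' @param b_sequence b-values in within-cycle acquisition order (s/mm^2)
#' @param directions matrix of unit row 3-vectors; default the six axis
#'   directions x, y, z, -x, -y, -z
#' @param n_cycles number of repeats of `b_sequence`
#' @param volume_interval seconds per acquired volume
#' @param c_of_b function mapping a b-value to its flow-encoding factor c
#'   (s/mm); default 0 everywhere (monopolar / flow-compensated encoding)
#' @param scan_id label stored with every acquisition
#' @return a `dwi_scheme` of `length(b_sequence) * n_cycles` acquisitions
#' @export
build_mixed_scheme <- function(b_sequence, directions = CANONICAL_DIRECTIONS,
                               n_cycles = 6L, volume_interval = 7.5,
                               c_of_b = function(b) 0 * b,
                               scan_id = "custom") {
  if (length(b_sequence) == 0) stop("b_sequence must be nonempty")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  directions <- as.matrix(directions)
  if (ncol(directions) != 3 || nrow(directions) == 0)
    stop("directions must be a nonempty matrix of 3-vectors")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("non-unit direction supplied")

  B <- length(b_sequence)
  K <- nrow(directions)
  L <- lcm2(B, K)
  steps <- seq_len(B * n_cycles) - 1L
  bi <- steps %% B
  ji <- (steps + steps %/% L) %% K
  b <- b_sequence[bi + 1L]
  dir <- directions[ji + 1L, , drop = FALSE]
  dir[b == 0, ] <- 0  # null direction sentinel for b = 0 repetitions
  new_scheme(b, dir, c_of_b(b), scan_id, volume_interval)
}

#' Interleave b-values in "low-high" order
#'
#' Alternately takes the smallest then the largest remaining value, e.g.
#' 0, 800, 5, 500, 10, 200, ... Spreads weak and strong diffusion weightings
#' evenly over the within-cycle sequence.
#'
#' @param b_values sorted ascending, unique b-values
#' @return reordered vector of the same values
#' @export
low_high_order <- function(b_values) {
  if (length(b_values) == 0) stop("empty b-value list")
  if (is.unsorted(b_values, strictly = TRUE))
    stop("b_values must be sorted ascending and unique")
  lo <- 1L
  hi <- length(b_values)
  out <- numeric(length(b_values))
  for (k in seq_along(b_values)) {
    if (k %% 2 == 1) {
      out[k] <- b_values[lo]; lo <- lo + 1L
    } else {
      out[k] <- b_values[hi]; hi <- hi - 1L
    }
  }
  out
}

direction_rank <- function(scheme) {
  d <- cbind(scheme$dx, scheme$dy, scheme$dz)
  rk <- integer(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (scheme$b[i] == 0) {
      rk[i] <- 0L
    } else {
      dif <- sweep(CANONICAL_DIRECTIONS, 2, d[i, ])
      m <- which.min(rowSums(dif^2))
      rk[i] <- m
    }
  }
  rk
}

#' Reorder a scheme by ascending b-value ("ordered" protocol)
#'
#' Produces the drift-sensitive acquisition order: sorted by ascending b, and
#' within each b-value the encoding directions in the canonical succession
#' x, y, z, -x, -y, -z (repetitions of the same pair kept in original order).
#' Indices and times are reassigned to the new order. The attribute
#' `source_index` records, for each new position, the 0-based index of the
#' acquisition in the input scheme (used to permute image data accordingly).
#'
#' @param scheme a `dwi_scheme`
#' @return a reordered `dwi_scheme` with attribute `source_index`
#' @export
ordered_scheme <- function(scheme) {
  validate_scheme(scheme)
  dr <- direction_rank(scheme)
  key <- paste(scheme$b, dr)
  rep_no <- stats::ave(seq_len(nrow(scheme)), key, FUN = seq_along)
  ord <- order(scheme$b, dr, rep_no)
  dirs <- as.matrix(scheme[ord, c("dx", "dy", "dz")])
  out <- new_scheme(scheme$b[ord], dirs, scheme$c[ord],
                    scheme$scan_id[ord], attr(scheme, "volume_interval"))
  attr(out, "source_index") <- scheme$n[ord]
  out
}

# flow-encoding factors for the non-flow-compensated bipolar encoding; a
# synthetic table (c grows as sqrt(b) at fixed gradient timing), since the
# waveform timings themselves are out of scope
nc_flow_encoding <- function(b, c_max = 0.35, b_ref = 200) {
  c_max * sqrt(b / b_ref)
}

#' Preset acquisition schemes for the three IVIM protocols
#'
#' * `"sivim"`: b = 0, 200, 800 s/mm^2 with 2, 3, 1 repetitions per cycle
#'   (implemented as the within-cycle sequence 0, 200, 800, 200, 0, 200),
#'   six cycles, 36 volumes, 4.5 min.
#' * `"diffusive"`: ten b-values 0, 5, 10, 20, 30, 50, 100, 200, 500,
#'   800 s/mm^2 in low-high order, six cycles, 60 volumes, 7.5 min.
#' * `"ballistic"`: a pair of schemes over seven b-values 0, 5, 10, 20, 30,
#'   100, 200 s/mm^2 in low-high order, six cycles each: a flow-compensated
#'   (FC, c = 0 everywhere) and a non-flow-compensated (NC, c > 0 for b > 0)
#'   scan; 84 volumes, 10.5 min combined.
#'
#' All presets use a 7.5 s volume interval so that scheme durations match the
#' protocol scan times.
#'
#' @param name one of `"sivim"`, `"diffusive"`, `"ballistic"`
#' @return a `dwi_scheme`, or for `"ballistic"` a list with elements `fc`
#'   and `nc`
#' @export
protocol_preset <- function(name = c("sivim", "diffusive", "ballistic")) {
  name <- match.arg(name)
  vi <- 7.5
  switch(name,
    sivim = build_mixed_scheme(c(0, 200, 800, 200, 0, 200),
                               volume_interval = vi, scan_id = "sIVIM"),
    diffusive = build_mixed_scheme(
      low_high_order(c(0, 5, 10, 20, 30, 50, 100, 200, 500, 800)),
      volume_interval = vi, scan_id = "diffusive"),
    ballistic = {
      bs <- low_high_order(c(0, 5, 10, 20, 30, 100, 200))
      list(
        fc = build_mixed_scheme(bs, volume_interval = vi,
                                scan_id = "ballistic-FC"),
        nc = build_mixed_scheme(bs, volume_interval = vi,
                                c_of_b = nc_flow_encoding,
                                scan_id = "ballistic-NC")
      )
    }
  )
}

#' Write a scheme as FSL-style bval/bvec text files
#'
#' `bval` holds one whitespace-delimited row of b-values, `bvec` three rows
#' (x, y, z components), and the optional `cval` sidecar one row of
#' flow-encoding factors (s/mm). Scheme metadata (volume interval, scan label)
#' goes to a JSON sidecar.
#'
#' @param scheme a `dwi_scheme`
#' @param bval_path,bvec_path output text paths
#' @param cval_path optional path for the flow-encoding factors
#' @param json_path optional path for the metadata sidecar
#' @return invisibly the scheme
#' @export
write_scheme <- function(scheme, bval_path, bvec_path, cval_path = NULL,
                         json_path = NULL) {
  writeLines(paste(sprintf("%.1f", scheme$b), collapse = " "), bval_path)
  vec_lines <- vapply(c("dx", "dy", "dz"), function(cl)
    paste(sprintf("%.6f", scheme[[cl]]), collapse = " "), character(1))
  writeLines(vec_lines, bvec_path)
  if (!is.null(cval_path))
    writeLines(paste(sprintf("%.6f", scheme$c), collapse = " "), cval_path)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(volume_interval = attr(scheme, "volume_interval"),
           scan_id = scheme$scan_id[1]),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(scheme)
}

parse_numeric_row <- function(line, path) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) stop("non-numeric token in ", path)
  vals
}

#' Read a scheme from FSL-style bval/bvec text files
#'
#' @param bval_path,bvec_path input text paths (1-row bval, 3-row bvec)
#' @param cval_path optional flow-encoding sidecar; defaults to c = 0
#' @param volume_interval seconds per volume (used for acquisition times);
#'   overridden by `json_path` if given
#' @param json_path optional metadata sidecar written by [write_scheme()]
#' @param scan_id label when no JSON sidecar is given
#' @return a `dwi_scheme`
#' @export
read_scheme <- function(bval_path, bvec_path, cval_path = NULL,
                        volume_interval = 7.5, json_path = NULL,
                        scan_id = "custom") {
  b <- parse_numeric_row(readLines(bval_path)[1], bval_path)
  vl <- readLines(bvec_path)
  if (length(vl) < 3) stop("bvec file must have three rows")
  vecs <- lapply(vl[1:3], parse_numeric_row, path = bvec_path)
  if (any(lengths(vecs) != length(b)))
    stop("length mismatch between bval and bvec")
  cv <- if (!is.null(cval_path)) {
    v <- parse_numeric_row(readLines(cval_path)[1], cval_path)
    if (length(v) != length(b)) stop("length mismatch between bval and cval")
    v
  } else rep(0, length(b))
  if (!is.null(json_path)) {
    meta <- jsonlite::read_json(json_path)
    volume_interval <- meta$volume_interval
    scan_id <- meta$scan_id
  }
  new_scheme(b, cbind(vecs[[1]], vecs[[2]], vecs[[3]]), cv,
             scan_id, volume_interval)
}
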