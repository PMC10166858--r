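#' Distance profile of one subsequence against all others
#'
#' Computes the multichannel z-normalized Euclidean distance from window
#' `query_idx` to every window in the all-subsequence set: each channel of
#' each window is z-normalized independently, per-channel squared Euclidean
#' distances are summed, and the square root taken. Entry `query_idx` is the
#' self-distance 0 (exclusion-zone masking is applied later, by [stamp()]).
#'
#' @param ss An `lss_subseq` from [extract_subsequences()].
#' @param query_idx Window index, 1-based.
#' @param epsilon Degeneracy threshold passed to the z-normalization.
#' @return Numeric vector of length `count(ss)`.
#' @export
distance_profile <- function(ss, query_idx, epsilon = 1e-12) {
  stopifnot(inherits(ss, "lss_subseq"))
  count <- dim(ss$windows)[1]
  if (length(query_idx) != 1L || !is.finite(query_idx) ||
      query_idx != round(query_idx) || query_idx < 1 || query_idx > count) {
    abort(sprintf("query_idx must be in [1, %d]; got %s", count, format(query_idx)))
  }
  z <- znorm_window_matrix(ss$source, ss$m, epsilon)
  d2 <- rowSums(sweep(z, 2, z[query_idx, ])^2)
  sqrt(pmax(d2, 0))
}

#' Mask a trivial-match exclusion zone in a distance profile
#'
#' Entries within `excl` positions of `center` (inclusive, on both sides) are
#' set to `Inf` so a subsequence cannot match itself or its near-identical
#' neighbors that share almost all of their samples.
#'
#' @param d Numeric vector (a distance profile).
#' @param center Position, 1-based.
#' @param excl Exclusion radius in positions, `>= 0`.
#' @return `d` with the zone masked.
#' @export
#' @examples
#' apply_exclusion(c(3, 1, 2, 5), center = 2, excl = 1)
apply_exclusion <- function(d, center, excl) {
  if (excl < 0) abort("excl must be >= 0")
  lo <- max(1L, center - excl)
  hi <- min(length(d), center + excl)
  if (lo <= hi) d[lo:hi] <- Inf
  d
}

default_exclusion <- function(m) as.integer(ceiling(m / 4))

#' Matrix profile of a multichannel time series (STAMP)
#'
#' For every subsequence, finds the distance to and index of its nearest
#' admissible neighbor under the multichannel z-normalized Euclidean
#' distance. Admissible partners `k` of window `j` satisfy
#' `|k - j| > excl` (no trivial matches), `|k - j| <= tc` when a finite
#' temporal constraint is set, and `k > j` in forward mode (arcs may only
#' point towards newer data, the FLOSS streaming restriction).
#'
#' Positions with no admissible partner (possible near the end of a forward
#' profile) carry `p = Inf` and `i = NA`; downstream arc counting skips them.
#' Ties in distance are broken towards the smallest admissible index, which
#' makes the result deterministic and order-independent.
#'
#' @param x Time series (data frame, matrix, or vector).
#' @param m Subsequence length in time steps.
#' @param tc Temporal-constraint radius in positions, or `Inf` for
#'   unconstrained. Must exceed `excl` when finite.
#' @param direction `"bidirectional"` (default) or `"forward"`.
#' @param excl Trivial-match exclusion radius; defaults to `ceiling(m / 4)`,
#'   the convention of standard matrix-profile implementations (the original
#'   description leaves it open).
#' @param epsilon Degeneracy threshold for window z-normalization.
#' @return An object of class `lss_matrix_profile`: list with `p` (distances),
#'   `i` (neighbor indices), `m`, `n`, `tc`, `direction`, `excl`.
#' @seealso [cac_from_profile()] to turn the index vector into a corrected
#'   arc curve, [lsmp_full()] for the latent-space analogue.
#' @export
#' @examples
#' x <- sin(seq(0, 20, length.out = 200)) + rnorm(200, sd = 0.05)
#' mp <- stamp(x, m = 16)
#' head(tidy(mp))
stamp <- function(x, m, tc = Inf,
                  direction = c("bidirectional", "forward"),
                  excl = NULL, epsilon = 1e-12) {
  direction <- match.arg(direction)
  xm <- as_ts_matrix(x)
  n <- nrow(xm)
  check_window_length(m, n)
  m <- as.integer(m)
  if (is.null(excl)) excl <- default_exclusion(m)
  excl <- as.integer(excl)
  if (excl < 0) abort("excl must be >= 0")
  if (is.finite(tc) && tc <= excl) {
    abort(sprintf(
      "temporal constraint tc (%s) must exceed the exclusion radius excl (%d): no admissible partners exist",
      format(tc), excl
    ))
  }
  z <- znorm_window_matrix(xm, m, epsilon)
  count <- nrow(z)
  rs <- rowSums(z^2)
  p <- rep(Inf, count)
  i <- rep(NA_integer_, count)
  block <- 256L
  for (start in seq(1L, count, by = block)) {
    qs <- start:min(start + block - 1L, count)
    # squared distances, columns = queries in this block
    d2 <- outer(rs, rep(1, length(qs))) - 2 * (z %*% t(z[qs, , drop = FALSE]))
    d2 <- sweep(d2, 2, rs[qs], "+")
    for (col in seq_along(qs)) {
      q <- qs[col]
      d <- sqrt(pmax(d2[, col], 0))
      d <- apply_exclusion(d, q, excl)
      if (is.finite(tc)) {
        lo <- max(1L, q - as.integer(tc))
        hi <- min(count, q + as.integer(tc))
        if (lo > 1L) d[1:(lo - 1L)] <- Inf
        if (hi < count) d[(hi + 1L):count] <- Inf
      }
      if (direction == "forward" && q + excl >= 1L) {
        d[1:min(count, q + excl)] <- Inf
      }
      best <- which.min(d) # first minimum = smallest admissible index
      if (length(best) == 1L && is.finite(d[best])) {
        p[q] <- d[best]
        i[q] <- best
      }
    }
  }
  new_matrix_profile(p, i, m = m, n = n, tc = tc, direction = direction,
                     excl = excl, distance = "znorm_euclidean")
}

new_matrix_profile <- function(p, i, m, n, tc, direction, excl, distance) {
  structure(
    list(p = p, i = i, m = m, n = n, tc = tc, direction = direction,
         excl = excl, distance = distance),
    class = "lss_matrix_profile"
  )
}

#' @export
print.lss_matrix_profile <- function(x, ...) {
  cat(sprintf(
    "<lss_matrix_profile> %d positions, m = %d, %s, tc = %s, excl = %d (%s distance)\n",
    length(x$p), x$m, x$direction,
    if (is.finite(x$tc)) format(x$tc) else "unconstrained",
    x$excl, x$distance
  ))
  invisible(x)
}

#' @describeIn stamp Tidy a matrix profile into a tibble with one row per
#'   subsequence position (`position`, `value`, `neighbor`).
#' @param x,... Method arguments.
#' @export
tidy.lss_matrix_profile <- function(x, ...) {
  tibble(position = seq_along(x$p), value = x$p, neighbor = x$i)
}

#' Channel-averaged corrected arc curve (FLUSS baseline)
#'
#' The FLUSS recipe for multichannel data: compute a single-channel matrix
#' profile and corrected arc curve on every channel independently, then
#' average the curves elementwise. Redundant or uninformative channels
#' dilute the signal -- the weakness the latent-space path is designed to
#' avoid -- but the average remains a strong baseline.
#'
#' @inheritParams stamp
#' @param n_trials,seed Monte-Carlo settings for the idealized arc curve when
#'   the profile is temporally constrained or forward-only.
#' @return Numeric vector in `[0, 1]`, class `lss_cac`, length `n - m + 1`.
#' @export
fluss_cac <- function(x, m, tc = Inf,
                      direction = c("bidirectional", "forward"),
                      excl = NULL, n_trials = 1000, seed = 1L) {
  direction <- match.arg(direction)
  xm <- as_ts_matrix(x)
  curves <- lapply(seq_len(ncol(xm)), function(ch) {
    mp <- stamp(xm[, ch, drop = FALSE], m = m, tc = tc,
                direction = direction, excl = excl)
    as.numeric(cac_from_profile(mp, n_trials = n_trials, seed = seed))
  })
  avg <- Reduce(`+`, curves) / length(curves)
  new_cac(avg, direction = direction, tc = tc)
}
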