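#' Arc curve: arc crossings over each position
#'
#' Every subsequence is linked to its nearest neighbor by an arc drawn over
#' the time axis; the arc curve counts, for each position, the arcs passing
#' strictly over it (endpoints do not count as crossings, so the curve is 0
#' at both ends of every arc). Inside homogeneous regimes most arcs stay
#' local and pile up; almost no arc crosses a regime boundary, which is the
#' signal the segmentation reads. Positions with the no-partner sentinel
#' (`NA`) contribute no arc.
#'
#' Implemented as an O(L) difference-array sweep.
#'
#' @param i Integer vector of nearest-neighbor indices (1-based, `NA` for
#'   no partner).
#' @return Numeric vector of crossing counts, same length.
#' @export
#' @examples
#' count_arcs(c(3L, 4L, 1L, 2L)) # two arcs cross each interior position
count_arcs <- function(i) {
  L <- length(i)
  j <- seq_len(L)
  ok <- !is.na(i)
  if (any(i[ok] < 1 | i[ok] > L)) abort("neighbor indices out of range")
  a <- pmin(j[ok], i[ok])
  b <- pmax(j[ok], i[ok])
  span <- b - a
  a <- a[span >= 2]
  b <- b[span >= 2]
  if (length(a) == 0) return(numeric(L))
  # +1 entering at a+1, -1 after b-1
  cumsum(tabulate(a + 1L, nbins = L) - tabulate(b, nbins = L))
}

# Sample, for every position j, one partner uniformly over the admissible
# set of the given direction / temporal constraint (self excluded). Positions
# with an empty admissible set get NA. Used by the simulated idealized arc
# curve; the admissible set deliberately matches the matrix-profile masking
# geometry so that the normalization is self-consistent.
sample_random_partners <- function(L, direction, tc) {
  j <- seq_len(L)
  if (direction == "forward") {
    lo <- j + 1
    hi <- if (is.finite(tc)) pmin(L, j + tc) else rep(L, L)
    size <- pmax(hi - lo + 1, 0)
    r <- floor(runif(L) * size)
    partner <- lo + r
  } else {
    lo <- if (is.finite(tc)) pmax(1, j - tc) else rep(1, L)
    hi <- if (is.finite(tc)) pmin(L, j + tc) else rep(L, L)
    size <- hi - lo # one slot removed for self
    r <- floor(runif(L) * size)
    partner <- lo + r + as.numeric(lo + r >= j)
  }
  partner[size <= 0] <- NA
  as.integer(partner)
}

#' Idealized arc curve
#'
#' The expected arc curve of a structureless series, used to normalize raw
#' arc counts. In the bidirectional unconstrained case it is the analytic
#' inverted parabola `2 k (L - 1 - k) / (L - 1)` (0-based position `k`),
#' whose height at the midpoint is half the curve length. No closed form is
#' available for forward-only or temporally constrained arcs (the forward
#' curve is skewed to the right, a constrained curve plateaus), so those are
#' estimated by Monte-Carlo: each trial draws one uniformly random admissible
#' partner per position and counts crossings; trials are averaged.
#'
#' The curve is clamped below at 1 before use as a divisor, so edge positions
#' where almost no random arc can cross never blow up the ratio.
#'
#' @param L Curve length (number of subsequence positions), `>= 3`.
#' @param direction `"bidirectional"` or `"forward"`.
#' @param tc Temporal-constraint radius or `Inf`.
#' @param n_trials Monte-Carlo trials for the simulated modes.
#' @param seed Seed for the simulated modes (deterministic given seed).
#' @return Object of class `lss_iac`: list with `iac` (clamped), `raw`
#'   (unclamped mean), `se` (per-position standard error, simulated modes
#'   only), `mode`, `direction`, `tc`, `n_trials`, `seed`.
#' @export
idealized_arc_curve <- function(L, direction = c("bidirectional", "forward"),
                                tc = Inf, n_trials = 1000, seed = 1L) {
  direction <- match.arg(direction)
  if (L < 3) abort("idealized arc curve needs L >= 3")
  L <- as.integer(L)
  analytic <- direction == "bidirectional" && !is.finite(tc)
  key <- paste(L, direction, format(tc), if (analytic) "a" else n_trials,
               if (analytic) "" else seed)
  if (is.null(the$iac_cache)) the$iac_cache <- new.env(parent = emptyenv())
  cached <- the$iac_cache[[key]]
  if (!is.null(cached)) return(cached)

  if (analytic) {
    k <- seq_len(L) - 1
    raw <- 2 * k * (L - 1 - k) / (L - 1)
    out <- structure(
      list(iac = pmax(raw, 1), raw = raw, se = NULL,
           mode = "bidirectional_analytic", direction = direction, tc = tc,
           n_trials = NA_integer_, seed = NA_integer_),
      class = "lss_iac"
    )
  } else {
    acc <- numeric(L)
    acc2 <- numeric(L)
    withr::with_seed(as.integer(seed), {
      for (t in seq_len(n_trials)) {
        ac <- count_arcs(sample_random_partners(L, direction, tc))
        acc <- acc + ac
        acc2 <- acc2 + ac^2
      }
    })
    raw <- acc / n_trials
    se <- sqrt(pmax(acc2 / n_trials - raw^2, 0) / n_trials)
    out <- structure(
      list(iac = pmax(raw, 1), raw = raw, se = se, mode = "simulated",
           direction = direction, tc = tc, n_trials = as.integer(n_trials),
           seed = as.integer(seed)),
      class = "lss_iac"
    )
  }
  the$iac_cache[[key]] <- out
  out
}

#' @export
print.lss_iac <- function(x, ...) {
  cat(sprintf("<lss_iac> length %d, %s (%s, tc = %s)\n",
              length(x$iac), x$mode, x$direction,
              if (is.finite(x$tc)) format(x$tc) else "unconstrained"))
  invisible(x)
}

new_cac <- function(values, direction, tc, iac_mode = NA_character_) {
  structure(as.numeric(values), class = "lss_cac",
            direction = direction, tc = tc, iac_mode = iac_mode)
}

#' Corrected arc curve
#'
#' Divides the raw arc counts by the idealized curve and clamps to `[0, 1]`:
#' `cac[k] = min(ac[k] / iac[k], 1)`. Values near 0 mean far fewer crossings
#' than a structureless series would produce -- evidence of a change-point.
#'
#' Edge positions carry no usable evidence and are reported as 1: where the
#' idealized count is small the ratio is noise, not signal. Treating each
#' crossing as roughly independent, the null sampling deviation of
#' `ac / iac` is about `1 / sqrt(iac)`, so requiring it below 0.2 gives the
#' default floor of 25 expected crossings. For the bidirectional parabola
#' this affects only a dozen positions at each end; for the right-skewed
#' one-directional curve it widens the protected margin at the stream head
#' and tail, where spurious valleys would otherwise appear.
#'
#' @param ac Numeric vector of arc counts ([count_arcs()]).
#' @param iac An `lss_iac` of the same length.
#' @param min_expected_arcs Positions whose unclamped idealized count falls
#'   below this are reported as 1 (no evidence).
#' @return Numeric vector of class `lss_cac`, values in `[0, 1]`.
#' @export
corrected_arc_curve <- function(ac, iac, min_expected_arcs = 25) {
  stopifnot(inherits(iac, "lss_iac"))
  if (length(ac) != length(iac$iac)) {
    abort(sprintf("arc curve length (%d) != idealized curve length (%d)",
                  length(ac), length(iac$iac)))
  }
  cac <- pmin(ac / iac$iac, 1)
  cac[iac$raw < min_expected_arcs] <- 1
  new_cac(cac, direction = iac$direction, tc = iac$tc, iac_mode = iac$mode)
}

#' Corrected arc curve of a matrix profile
#'
#' Convenience composition: count the arc crossings of the profile's index
#' vector, build the idealized curve matching the profile's direction and
#' temporal constraint, and normalize.
#'
#' @param mp An `lss_matrix_profile` (raw or latent-space).
#' @param n_trials,seed Monte-Carlo settings for non-analytic idealized
#'   curves.
#' @param min_expected_arcs Edge-evidence floor, see [corrected_arc_curve()].
#' @return `lss_cac` vector.
#' @export
cac_from_profile <- function(mp, n_trials = 1000, seed = 1L,
                             min_expected_arcs = 25) {
  stopifnot(inherits(mp, "lss_matrix_profile"))
  L <- length(mp$i)
  ac <- count_arcs(mp$i)
  iac <- idealized_arc_curve(L, direction = mp$direction, tc = mp$tc,
                             n_trials = n_trials, seed = seed)
  corrected_arc_curve(ac, iac, min_expected_arcs = min_expected_arcs)
}

#' @export
print.lss_cac <- function(x, ...) {
  cat(sprintf("<lss_cac> length %d (%s, tc = %s), min %.3f at %d\n",
              length(x), attr(x, "direction"),
              if (is.finite(attr(x, "tc"))) format(attr(x, "tc")) else "unconstrained",
              min(x), which.min(x)))
  invisible(x)
}

#' @export
as_tibble.lss_cac <- function(x, ...) {
  tibble(position = seq_along(x), cac = as.numeric(x))
}
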