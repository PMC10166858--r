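#' Regime Extraction Algorithm (REA)
#'
#' Extracts the `k` lowest "valley" points of a corrected arc curve:
#' repeatedly take the global minimum, record it, and mask an exclusion zone
#' of `excl_width` positions on both sides so the remaining picks cannot
#' fall into the same valley. Requires the number of change-points to be
#' known; the local variants relax the global-minimum behavior and the
#' threshold variant drops the known-count requirement.
#'
#' @param cac Numeric vector (a corrected arc curve or any score where low
#'   means change-point).
#' @param k Number of change-points to extract, `>= 1`.
#' @param excl_width Exclusion radius in positions. The reference default is
#'   five subsequence lengths (`5 * NW`).
#' @return Sorted integer vector of at most `k` indices; a warning is issued
#'   if the exclusion zones exhaust the curve first.
#' @export
#' @examples
#' curve <- rep(1, 100); curve[40] <- 0; curve[80] <- 0.2
#' rea(curve, k = 2, excl_width = 10)
rea <- function(cac, k, excl_width) {
  if (k < 1) abort("k must be >= 1")
  x <- as.numeric(cac)
  if (length(x) == 0) abort("cac is empty")
  found <- integer(0)
  for (j in seq_len(k)) {
    idx <- which.min(x)
    if (length(idx) == 0 || !is.finite(x[idx])) {
      warn(sprintf("only %d of %d requested change-points are extractable under the exclusion zones",
                   length(found), k))
      break
    }
    found <- c(found, idx)
    x <- apply_exclusion(x, idx, excl_width)
  }
  sort(found)
}

#' Locally scale a corrected arc curve
#'
#' Standardizes each position of the curve to zero mean and unit variance
#' using rolling statistics, so valleys are judged against their local
#' neighborhood rather than the whole series -- essential for long
#' recordings where the curve's baseline drifts. `"centered"` mode uses the
#' window `[j - local_window, j + local_window]` (truncated at the
#' boundaries); `"trailing"` uses `[j - 2 * local_window, j]`, i.e. only
#' past values, which is the form a streaming consumer can compute.
#' Positions whose rolling standard deviation is degenerate map to 0.
#'
#' @param cac Numeric vector.
#' @param local_window Rolling half-width in positions, `>= 2`. A practical
#'   choice is the mean gap between known change-points of a training set.
#' @param scaling_mode `"centered"` or `"trailing"`.
#' @return List of class `lss_scaled_cac`: `values`, `mu`, `sigma`.
#' @export
scale_cac <- function(cac, local_window,
                      scaling_mode = c("centered", "trailing")) {
  scaling_mode <- match.arg(scaling_mode)
  if (local_window < 2) abort("local_window must be >= 2")
  x <- as.numeric(cac)
  L <- length(x)
  w <- as.integer(local_window)
  j <- seq_len(L)
  if (scaling_mode == "centered") {
    lo <- pmax(1L, j - w); hi <- pmin(L, j + w)
  } else {
    lo <- pmax(1L, j - 2L * w); hi <- j
  }
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1L] - cs[lo]) / cnt
  ms <- (cs2[hi + 1L] - cs2[lo]) / cnt
  sigma <- sqrt(pmax(ms - mu^2, 0))
  # degeneracy is judged relative to the local magnitude: the cumulative-sum
  # variance cancels catastrophically on flat stretches, leaving O(1e-7)
  # artifacts that must not be standardized into spurious structure
  flat <- sigma < pmax(1e-12, 1e-7 * sqrt(pmax(ms, 0)))
  vals <- ifelse(flat, 0, (x - mu) / sigma)
  structure(list(values = vals, mu = mu, sigma = sigma,
                 local_window = w, scaling_mode = scaling_mode),
            class = "lss_scaled_cac")
}

#' Local Regime Extraction Algorithm (LREA)
#'
#' [rea()] applied to the locally scaled curve ([scale_cac()], centered
#' mode): the `k` valleys lowest *relative to their neighborhood* are
#' extracted, which usually beats the global criterion on long series whose
#' change-points are spread roughly evenly in time. As `local_window` grows
#' the scaling becomes global and LREA tends to REA.
#'
#' @inheritParams rea
#' @inheritParams scale_cac
#' @return Sorted integer vector of at most `k` indices.
#' @export
lrea <- function(cac, k, local_window, excl_width) {
  sc <- scale_cac(cac, local_window, "centered")
  rea(sc$values, k, excl_width)
}

#' Local Threshold Extraction Algorithm (LTEA)
#'
#' Count-free, online-capable extraction: the curve is locally scaled, every
#' value above `threshold` is set to 1 (disregarded), the remaining maximal
#' runs of consecutive sub-threshold values form valleys, and each valley
#' contributes the index of its minimum. Valleys whose minima fall within
#' `excl_width` of an already accepted deeper minimum are dropped. With the
#' scaled curve standardized to unit variance, a threshold around -1 (one
#' standard deviation below the local mean) is a good default.
#'
#' @inheritParams scale_cac
#' @param threshold Cut on the scaled curve, must be `< 1`; default `-1`.
#' @param excl_width Exclusion radius in positions.
#' @param scaling_mode `"trailing"` (streaming-compatible, default) or
#'   `"centered"`.
#' @return Sorted integer vector of change-point indices (possibly empty).
#' @export
ltea <- function(cac, local_window, threshold = -1, excl_width,
                 scaling_mode = c("trailing", "centered")) {
  scaling_mode <- match.arg(scaling_mode)
  if (threshold >= 1) abort("threshold must be < 1 (1 is the disregarded value)")
  s <- scale_cac(cac, local_window, scaling_mode)$values
  s[s > threshold] <- 1
  runs <- rle(s == 1)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  mins <- integer(0)
  depths <- numeric(0)
  for (v in which(!runs$values)) {
    seg <- starts[v]:ends[v]
    at <- seg[which.min(s[seg])]
    mins <- c(mins, at)
    depths <- c(depths, s[at])
  }
  accepted <- integer(0)
  for (cand in mins[order(depths, mins)]) {   # deepest first, ties -> earlier
    if (all(abs(accepted - cand) > excl_width)) accepted <- c(accepted, cand)
  }
  sort(accepted)
}
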