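#' Coerce a time series to its internal matrix form
#'
#' User-facing functions in latentseg accept a multichannel time series as a
#' data frame (one row per time step, one numeric column per channel), a
#' numeric matrix of the same shape, or a bare numeric vector (a single
#' channel). This helper validates the input and returns the numeric matrix
#' the numeric cores operate on.
#'
#' All values must be finite: the method has no missing-data support, and a
#' single NA would silently poison every distance computed from the window
#' containing it.
#'
#' @param x Data frame, numeric matrix, or numeric vector.
#' @return Numeric matrix, `n` rows (time steps) by `NC` columns (channels),
#'   with channel names preserved when present.
#' @export
#' @examples
#' as_ts_matrix(data.frame(acc = sin(1:50), gyr = cos(1:50)))[1:3, ]
as_ts_matrix <- function(x) {
  if (is.data.frame(x)) {
    non_num <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(non_num) > 0) {
      abort(paste0(
        "all channels must be numeric; non-numeric column(s): ",
        paste(non_num, collapse = ", ")
      ))
    }
    x <- as.matrix(x)
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, ncol = 1)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("time series must be a data frame, numeric matrix, or numeric vector")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("time series must have at least one row and one channel")
  }
  if (!all(is.finite(x))) {
    abort("time series contains non-finite values; missing data are not supported")
  }
  storage.mode(x) <- "double"
  x
}

#' Extract the all-subsequence set of a time series
#'
#' Slides a window of length `m` over the series with step size 1, yielding
#' `n - m + 1` subsequences. Window `j` covers rows `j` to `j + m - 1`
#' (1-based, inclusive), so concatenating the first row of every window plus
#' the tail of the last window reconstructs the series exactly.
#'
#' @param x Time series (data frame, matrix, or vector); see [as_ts_matrix()].
#' @param m Subsequence length in time steps, `2 <= m <= n`.
#' @return An object of class `lss_subseq`: a list with `windows` (array of
#'   dim `count x m x NC`), `m`, `n`, `nc`, and `source` (the series matrix).
#' @export
#' @examples
#' ss <- extract_subsequences(matrix(rnorm(20), ncol = 2), m = 4)
#' dim(ss$windows) # 7 windows of 4 steps x 2 channels
extract_subsequences <- function(x, m) {
  xm <- as_ts_matrix(x)
  n <- nrow(xm)
  check_window_length(m, n)
  m <- as.integer(m)
  count <- n - m + 1L
  nc <- ncol(xm)
  # idx[k, j] = source row of step k in window j
  idx <- outer(seq_len(m) - 1L, seq_len(count), "+")
  w <- array(0, dim = c(count, m, nc))
  for (ch in seq_len(nc)) {
    w[, , ch] <- t(matrix(xm[, ch][idx], nrow = m))
  }
  structure(
    list(windows = w, m = m, n = n, nc = nc, source = xm),
    class = "lss_subseq"
  )
}

#' @export
print.lss_subseq <- function(x, ...) {
  cat(sprintf(
    "<lss_subseq> %d windows of length %d over %d channel(s) (n = %d)\n",
    dim(x$windows)[1], x$m, x$nc, x$n
  ))
  invisible(x)
}

check_window_length <- function(m, n) {
  if (length(m) != 1L || !is.finite(m) || m != round(m) || m < 2 || m > n) {
    abort(sprintf(
      "subsequence length m must be an integer with 2 <= m <= n; got m = %s, n = %d",
      format(m), n
    ))
  }
  invisible(TRUE)
}

#' Z-normalize one subsequence window
#'
#' Each channel is independently shifted to mean zero and scaled to unit
#' standard deviation (population convention, denominator `m`). A channel
#' whose standard deviation falls below `epsilon` is degenerate --
#' essentially constant -- and is mapped to all zeros, which keeps distances
#' between such windows finite and is the convention of the widely used
#' matrix-profile implementations.
#'
#' @param w Numeric matrix, `m x NC` (a single window), or a numeric vector
#'   for one channel.
#' @param epsilon Degeneracy threshold for the standard deviation.
#' @return Matrix of the same shape.
#' @export
znormalize_window <- function(w, epsilon = 1e-12) {
  if (is.null(dim(w))) w <- matrix(w, ncol = 1)
  if (nrow(w) < 2) abort("window must have at least 2 rows to z-normalize")
  mu <- colMeans(w)
  centered <- sweep(w, 2, mu)
  sdev <- sqrt(colMeans(centered^2))
  out <- centered
  for (ch in seq_len(ncol(w))) {
    out[, ch] <- if (sdev[ch] < epsilon) 0 else centered[, ch] / sdev[ch]
  }
  out
}

# Flattened z-normalized window matrix: row j is window j with every channel
# z-normalized (population sd, degenerate channels -> 0), channels
# concatenated. Multichannel z-normalized Euclidean distance between windows
# is then the plain Euclidean distance between rows.
znorm_window_matrix <- function(xm, m, epsilon = 1e-12) {
  n <- nrow(xm)
  nc <- ncol(xm)
  count <- n - m + 1L
  out <- matrix(0, nrow = count, ncol = m * nc)
  idx <- outer(seq_len(m) - 1L, seq_len(count), "+")
  for (ch in seq_len(nc)) {
    wc <- matrix(xm[, ch][idx], nrow = m) # m x count
    mu <- colMeans(wc)
    wc <- sweep(wc, 2, mu)
    sdev <- sqrt(colMeans(wc^2))
    ok <- sdev >= epsilon
    wc[, ok] <- sweep(wc[, ok, drop = FALSE], 2, sdev[ok], "/")
    wc[, !ok] <- 0
    out[, (ch - 1L) * m + seq_len(m)] <- t(wc)
  }
  out
}

#' Validate a change-point set
#'
#' Change-points are strictly increasing 1-based time indices; a change-point
#' at index `t` means the first sample of the new regime is at `t`.
#'
#' @param cp Integer vector of change-point indices.
#' @param n Series length they refer to (optional; bounds checked if given).
#' @return The validated integer vector.
#' @export
validate_changepoints <- function(cp, n = NULL) {
  if (length(cp) == 0) return(integer(0))
  if (any(!is.finite(cp)) || any(cp != round(cp))) {
    abort("change-points must be finite integers")
  }
  cp <- as.integer(cp)
  if (any(diff(cp) <= 0)) abort("change-points must be strictly increasing")
  if (!is.null(n) && (cp[1] < 1L || cp[length(cp)] > n)) {
    abort(sprintf("change-points must lie in [1, %d]", n))
  }
  cp
}
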