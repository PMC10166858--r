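#' Latent-space distance profile
#'
#' Plain (non-z-normalized) Euclidean distances from one latent vector to all
#' latent vectors inside its temporal-constraint band; the exclusion zone and
#' everything outside the band carry the `Inf` sentinel. The latent rows are
#' already a learned representation, so no per-window normalization is
#' applied -- this is the deliberate difference from the raw-subsequence
#' distance profile.
#'
#' @param f Latent matrix (rows = subsequence positions), e.g. from
#'   [encode_all()].
#' @param query_idx Row index, 1-based.
#' @param tc Temporal-constraint radius in positions (finite, required).
#' @param excl Trivial-match exclusion radius, `< tc`.
#' @return Numeric vector of length `nrow(f)`.
#' @export
latent_distance_profile <- function(f, query_idx, tc, excl = 0L) {
  f <- as.matrix(f)
  N <- nrow(f)
  if (length(query_idx) != 1L || query_idx < 1 || query_idx > N ||
      query_idx != round(query_idx)) {
    abort(sprintf("query_idx must be in [1, %d]", N))
  }
  check_tc_excl(tc, excl)
  lo <- max(1L, as.integer(query_idx - tc))
  hi <- min(N, as.integer(query_idx + tc))
  d <- rep(Inf, N)
  band <- lo:hi
  delta <- sweep(f[band, , drop = FALSE], 2, f[query_idx, ])
  d[band] <- sqrt(rowSums(delta^2))
  apply_exclusion(d, as.integer(query_idx), as.integer(excl))
}

check_tc_excl <- function(tc, excl) {
  if (!is.finite(tc) || tc < 1) {
    abort("the latent-space matrix profile requires a finite temporal constraint tc >= 1")
  }
  if (excl < 0) abort("excl must be >= 0")
  if (tc <= excl) {
    abort(sprintf("tc (%s) must exceed excl (%s): no admissible partners exist",
                  format(tc), format(excl)))
  }
  invisible(TRUE)
}

# Core banded nearest-neighbor sweep shared by the full, batched and online
# paths. Scans inter-row offsets once per direction; processing backward
# partners in increasing partner order, then forward partners likewise, with
# strict improvement, implements the smallest-admissible-index tie rule.
lsmp_core <- function(f, tc, direction, excl) {
  N <- nrow(f)
  p <- rep(Inf, N)
  i <- rep(NA_integer_, N)
  offsets <- seq.int(excl + 1L, min(tc, N - 1L))
  if (excl + 1L > min(tc, N - 1L)) offsets <- integer(0)
  if (direction == "bidirectional") {
    for (d in rev(offsets)) {
      dd <- sqrt(rowSums((f[seq_len(N - d), , drop = FALSE] -
                            f[(d + 1L):N, , drop = FALSE])^2))
      rows <- (d + 1L):N
      upd <- dd < p[rows]
      p[rows][upd] <- dd[upd]
      i[rows][upd] <- rows[upd] - d
    }
  }
  for (d in offsets) {
    dd <- sqrt(rowSums((f[seq_len(N - d), , drop = FALSE] -
                          f[(d + 1L):N, , drop = FALSE])^2))
    rows <- seq_len(N - d)
    upd <- dd < p[rows]
    p[rows][upd] <- dd[upd]
    i[rows][upd] <- rows[upd] + d
  }
  list(p = p, i = i)
}

#' Latent-space matrix profile (LSMP)
#'
#' Nearest-neighbor profile over latent vectors: for every row of `f`, the
#' minimum Euclidean distance to (and index of) another row within the
#' temporal-constraint band, outside the exclusion zone, and -- in forward
#' mode -- strictly later in time. The temporal constraint is mandatory
#' here: it makes repeated regime types segmentable and bounds the distance
#' computation to a band.
#'
#' @inheritParams latent_distance_profile
#' @param direction `"bidirectional"` or `"forward"`.
#' @param excl Exclusion radius; defaults to `ceiling(m / 4)` subsequence
#'   positions when `f` carries an `m` attribute (adjacent windows share
#'   `m - 1` samples and stay near-duplicates after encoding).
#' @return An `lss_matrix_profile` with latent Euclidean distances.
#' @export
lsmp_full <- function(f, tc, direction = c("bidirectional", "forward"),
                      excl = NULL) {
  direction <- match.arg(direction)
  m <- attr(f, "m")
  f <- as.matrix(f)
  if (is.null(excl)) {
    if (is.null(m)) abort("excl must be supplied when f carries no window-length attribute")
    excl <- default_exclusion(m)
  }
  check_tc_excl(tc, excl)
  res <- lsmp_core(f, as.integer(tc), direction, as.integer(excl))
  new_matrix_profile(res$p, res$i, m = m %||% NA_integer_,
                     n = nrow(f) + (m %||% 1L) - 1L,
                     tc = as.integer(tc), direction = direction,
                     excl = as.integer(excl), distance = "latent_euclidean")
}

#' Memory-bounded LSMP via batched collapse
#'
#' Processes the latent rows in consecutive chunks of `t_lim` rows. Each
#' chunk's banded distance computation is extended backwards over the
#' overlap the merge re-derives (`2 tc - 1` trailing positions
#' bidirectionally, `tc` in forward mode, where earlier rows can point into
#' the new chunk), collapsed to a partial profile, and merged into the
#' running profile by elementwise minimum. The result is identical to
#' [lsmp_full()] on the whole matrix, but no more than one chunk's band is
#' ever materialized.
#'
#' @inheritParams lsmp_full
#' @param t_lim Chunk length in rows; must exceed `2 * tc` so each chunk
#'   covers the overlap it re-derives.
#' @return An `lss_matrix_profile`; attribute `max_dist_entries` records the
#'   largest number of distance entries materialized at once (memory
#'   instrumentation).
#' @export
batched_collapse <- function(f, t_lim, tc,
                             direction = c("bidirectional", "forward"),
                             excl = NULL) {
  direction <- match.arg(direction)
  m <- attr(f, "m")
  f <- as.matrix(f)
  if (is.null(excl)) {
    if (is.null(m)) abort("excl must be supplied when f carries no window-length attribute")
    excl <- default_exclusion(m)
  }
  check_tc_excl(tc, excl)
  tc <- as.integer(tc); excl <- as.integer(excl); t_lim <- as.integer(t_lim)
  if (t_lim <= 2L * tc) {
    abort(sprintf("t_lim (%d) must exceed 2 * tc (%d)", t_lim, 2L * tc))
  }
  N <- nrow(f)
  ov <- if (direction == "bidirectional") 2L * tc - 1L else tc
  p <- rep(Inf, N)
  i <- rep(NA_integer_, N)
  max_entries <- 0
  start <- 1L
  while (start <= N) {
    chunk_end <- min(start + t_lim - 1L, N)
    win_lo <- max(1L, start - ov)
    win <- win_lo:chunk_end
    res <- lsmp_core(f[win, , drop = FALSE], tc, direction, excl)
    max_entries <- max(max_entries, length(win))
    upd <- res$p < p[win]
    p[win][upd] <- res$p[upd]
    i[win][upd] <- res$i[upd] + win_lo - 1L
    start <- chunk_end + 1L
  }
  out <- new_matrix_profile(p, i, m = m %||% NA_integer_,
                            n = N + (m %||% 1L) - 1L, tc = tc,
                            direction = direction, excl = excl,
                            distance = "latent_euclidean")
  attr(out, "max_dist_entries") <- max_entries
  out
}

#' Streaming LSMP state
#'
#' Initializes the online latent-space matrix profile from an initial block
#' of latent rows. [lsmp_online_append()] then extends it incrementally:
#' after any sequence of appends the profile equals the offline result on the
#' concatenated rows. The state retains only a trailing buffer of rows
#' (`2 tc - 1` bidirectional, `tc` forward), so memory does not grow with
#' the part of the stream already summarized -- that is what makes the
#' epsilon-real-time operation possible, with epsilon the number of samples
#' accumulated between appends.
#'
#' @inheritParams lsmp_full
#' @param f_init Initial latent rows (at least one).
#' @return Object of class `lss_lsmp_state` with elements `p`, `i`,
#'   `n_rows`, `tc`, `direction`, `excl`, `buffer`.
#' @export
lsmp_online_init <- function(f_init, tc,
                             direction = c("bidirectional", "forward"),
                             excl = 0L) {
  direction <- match.arg(direction)
  f_init <- as.matrix(f_init)
  if (nrow(f_init) < 1L) abort("f_init must contain at least one row")
  check_tc_excl(tc, excl)
  tc <- as.integer(tc); excl <- as.integer(excl)
  res <- lsmp_core(f_init, tc, direction, excl)
  keep <- if (direction == "bidirectional") 2L * tc - 1L else tc
  nb <- min(nrow(f_init), keep)
  structure(
    list(p = res$p, i = res$i, n_rows = nrow(f_init), tc = tc,
         direction = direction, excl = excl, keep = keep,
         buffer = f_init[nrow(f_init) - nb + seq_len(nb), , drop = FALSE],
         latent_dim = ncol(f_init)),
    class = "lss_lsmp_state"
  )
}

#' Append latent rows to a streaming LSMP
#'
#' Extends the profile by the new rows and updates every affected existing
#' entry: a trailing entry's distance can only decrease when a new row lands
#' inside its band (elementwise minimum over a growing set of admissible
#' pairs). In forward mode entries never change once their band has been
#' fully observed.
#'
#' @param state An `lss_lsmp_state`.
#' @param new_rows Matrix of new latent rows (possibly zero rows).
#' @return Updated state.
#' @export
lsmp_online_append <- function(state, new_rows) {
  stopifnot(inherits(state, "lss_lsmp_state"))
  new_rows <- as.matrix(new_rows)
  if (nrow(new_rows) == 0L) return(state)
  if (ncol(new_rows) != state$latent_dim) {
    abort(sprintf("new rows have %d columns; state expects latent_dim = %d",
                  ncol(new_rows), state$latent_dim))
  }
  tc <- state$tc; excl <- state$excl
  nb <- nrow(state$buffer)
  r <- nrow(new_rows)
  fc <- rbind(state$buffer, new_rows)    # local rows 1..(nb + r)
  off <- state$n_rows - nb               # global = local + off
  Nl <- nb + r
  p <- c(state$p, rep(Inf, r))
  i <- c(state$i, rep(NA_integer_, r))
  offsets <- seq.int(excl + 1L, min(tc, Nl - 1L))
  if (excl + 1L > min(tc, Nl - 1L)) offsets <- integer(0)
  if (state$direction == "bidirectional") {
    # backward partners of the new rows, most distant first
    for (d in rev(offsets)) {
      t_lo <- max(1L, nb - d + 1L)
      t_hi <- Nl - d
      if (t_lo > t_hi) next
      ts_ <- t_lo:t_hi
      dd <- sqrt(rowSums((fc[ts_, , drop = FALSE] -
                            fc[ts_ + d, , drop = FALSE])^2))
      rows <- ts_ + d + off
      upd <- dd < p[rows]
      p[rows][upd] <- dd[upd]
      i[rows][upd] <- ts_[upd] + off
    }
  }
  # forward partners: every pair whose later endpoint is new
  for (d in offsets) {
    t_lo <- max(1L, nb - d + 1L)
    t_hi <- Nl - d
    if (t_lo > t_hi) next
    ts_ <- t_lo:t_hi
    dd <- sqrt(rowSums((fc[ts_, , drop = FALSE] -
                          fc[ts_ + d, , drop = FALSE])^2))
    rows <- ts_ + off
    upd <- dd < p[rows]
    p[rows][upd] <- dd[upd]
    i[rows][upd] <- ts_[upd] + d + off
  }
  n_total <- state$n_rows + r
  nb_new <- min(Nl, state$keep)
  state$p <- p
  state$i <- i
  state$n_rows <- n_total
  state$buffer <- fc[Nl - nb_new + seq_len(nb_new), , drop = FALSE]
  state
}

#' @export
print.lss_lsmp_state <- function(x, ...) {
  cat(sprintf(
    "<lss_lsmp_state> %d rows seen (%s, tc = %d, excl = %d), buffer %d rows\n",
    x$n_rows, x$direction, x$tc, x$excl, nrow(x$buffer)
  ))
  invisible(x)
}

#' Extract the matrix profile accumulated by a streaming state
#'
#' @param state An `lss_lsmp_state`.
#' @param m Window length to record on the profile (optional).
#' @return An `lss_matrix_profile`.
#' @export
lsmp_online_profile <- function(state, m = NA_integer_) {
  new_matrix_profile(state$p, state$i, m = m,
                     n = state$n_rows + max(1L, m, na.rm = TRUE) - 1L,
                     tc = state$tc, direction = state$direction,
                     excl = state$excl, distance = "latent_euclidean")
}

#' LFMD baseline: change-points from adjacent-window latent distances
#'
#' The Latent Feature Maximal Distance baseline encodes consecutive windows
#' (step `m - overlap`), computes the Euclidean distance between each
#' adjacent pair of latent vectors, and reports the local maxima of that
#' distance curve that exceed its global mean, thinned by an exclusion
#' radius of one window. Maxima are mapped back to series indices at the
#' window boundary they straddle.
#'
#' @param x Series to segment.
#' @param model Trained `lss_autoencoder`.
#' @param overlap Overlap between consecutive windows in samples,
#'   `0 <= overlap < nw`.
#' @return Integer vector of predicted change-point indices (possibly
#'   empty), with the distance curve attached as attribute `distance_curve`.
#' @export
lfmd_changepoints <- function(x, model, overlap = 0L) {
  stopifnot(inherits(model, "lss_autoencoder"))
  m <- model$spec$nw
  if (overlap < 0 || overlap >= m) {
    abort(sprintf("overlap must satisfy 0 <= overlap < nw = %d", m))
  }
  step <- m - as.integer(overlap)
  xm <- as_ts_matrix(x)
  n <- nrow(xm)
  if (n < 2L * m - overlap) abort("series too short for two windows")
  starts <- seq(1L, n - m + 1L, by = step)
  Xs <- apply_scaler(xm, model$scaler)
  tens <- window_tensor(Xs, m, step)
  z <- ae_encode_batch(model$spec, model$params, tens)
  dcurve <- sqrt(rowSums((z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE])^2))
  # the noise floor is set by the latent magnitude, not the curve itself:
  # identical windows can encode with O(1e-16) discrepancies
  lift <- mean(dcurve) + 1e-9 * max(1, abs(z))
  if (length(dcurve) < 3L || max(dcurve) <= lift) {
    peaks <- integer(0)
  } else {
    interior <- 2:(length(dcurve) - 1L)
    strict <- interior[dcurve[interior] > dcurve[interior - 1L] &
                         dcurve[interior] > dcurve[interior + 1L] &
                         dcurve[interior] > lift]
    excl_r <- max(1L, as.integer(ceiling(m / step)))
    peaks <- integer(0)
    for (cand in strict[order(dcurve[strict], decreasing = TRUE)]) {
      if (all(abs(peaks - cand) > excl_r)) peaks <- c(peaks, cand)
    }
    peaks <- sort(peaks)
  }
  cp <- starts[peaks + 1L] # first sample of the window after the jump
  structure(as.integer(cp), distance_curve = dcurve)
}
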