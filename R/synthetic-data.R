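#' Latent-source generators for synthetic regimes
#'
#' A synthetic regime is a set of latent sources, each with its own
#' generator; segments of that regime synthesize fresh source paths, mix
#' them into the observed channels, and so share spectral/autoregressive
#' structure without repeating waveforms. Three generator kinds cover the
#' qualitative behaviors of biosignal channels:
#'
#' * `src_sinusoid()`: oscillation at a fixed frequency (cycles per step)
#'   with a fresh random phase per segment (`phase_jitter` bounds it);
#' * `src_ar()`: an autoregressive process with the given coefficients,
#'   restarted per segment, capturing colored-noise/resonant dynamics;
#' * `src_burst()`: sparse random impulses at `rate` per step, convolved
#'   with an exponential envelope of the given `decay` (steps), mimicking
#'   burst-like muscle activation.
#'
#' Every source path is standardized to zero mean, unit variance over its
#' segment and then multiplied by `amplitude`, so relative amplitudes are
#' interpretable across kinds.
#'
#' @param freq Sinusoid frequency in cycles per time step.
#' @param amplitude Scale applied after standardization.
#' @param phase_jitter Half-range of the uniform random phase (radians).
#' @param coef AR coefficient vector.
#' @param rate Expected impulses per step, in (0, 1).
#' @param decay Envelope decay constant in steps.
#' @return A source-spec list, for use in [regime_spec()].
#' @name synthetic-sources
NULL

#' @rdname synthetic-sources
#' @export
src_sinusoid <- function(freq, amplitude = 1, phase_jitter = pi) {
  list(kind = "sinusoid", freq = freq, amplitude = amplitude,
       phase_jitter = phase_jitter)
}

#' @rdname synthetic-sources
#' @export
src_ar <- function(coef, amplitude = 1) {
  list(kind = "ar", coef = coef, amplitude = amplitude)
}

#' @rdname synthetic-sources
#' @export
src_burst <- function(rate, decay = 10, amplitude = 1) {
  list(kind = "burst", rate = rate, decay = decay, amplitude = amplitude)
}

#' Define a synthetic regime
#'
#' @param id Regime label.
#' @param sources List of source specs ([src_sinusoid()], [src_ar()],
#'   [src_burst()]); one latent source path is synthesized per entry for
#'   every segment of this regime.
#' @return Object of class `lss_regime`.
#' @export
regime_spec <- function(id, sources) {
  structure(list(id = id, sources = sources), class = "lss_regime")
}

#' Default EMG-like regime set
#'
#' Five regimes over three latent sources each: a regime-specific sinusoid
#' (disjoint frequencies), a resonant AR(2) process whose pole angle moves
#' with the regime, and a burst source whose rate and envelope vary. The
#' disjoint spectra make regimes distinguishable through short windows; how
#' distinguishable is controlled at mixing time by the observation noise.
#'
#' @param n_regimes Number of regimes (up to 8 distinct parameter slots).
#' @return List of `lss_regime` objects.
#' @export
default_emg_regimes <- function(n_regimes = 5) {
  if (n_regimes < 1 || n_regimes > 8) abort("n_regimes must be in 1..8")
  lapply(seq_len(n_regimes), function(r) {
    theta <- 2 * pi * (0.04 + 0.035 * r)
    rho <- 0.95
    regime_spec(
      id = paste0("R", r),
      sources = list(
        src_sinusoid(freq = 0.015 + 0.012 * (r - 1)),
        src_ar(coef = c(2 * rho * cos(theta), -rho^2)),
        src_burst(rate = 0.02 + 0.01 * r, decay = 4 + 2 * r)
      )
    )
  })
}

synth_source <- function(src, dur) {
  x <- switch(src$kind,
    sinusoid = {
      phase <- runif(1, -src$phase_jitter, src$phase_jitter)
      sin(2 * pi * src$freq * seq_len(dur) + phase)
    },
    ar = {
      as.numeric(stats::arima.sim(list(ar = src$coef), n = dur,
                                  n.start = 200))
    },
    burst = {
      spikes <- stats::rbinom(dur, 1, src$rate) * rnorm(dur)
      env <- exp(-(0:min(dur - 1, ceiling(6 * src$decay))) / src$decay)
      le <- length(env)
      padded <- stats::filter(c(numeric(le - 1), spikes), env, sides = 1)
      as.numeric(padded)[le:(le - 1 + dur)]
    },
    abort(sprintf("unknown source kind '%s'", src$kind))
  )
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, dur))
  src$amplitude * (x - mean(x)) / s
}

#' Fixed virtual sensor-array mixing matrix
#'
#' Deterministic mixing from latent sources to observed channels (rows
#' normalized to unit norm), shared by default between training clips and
#' evaluation series so they represent the same virtual sensor array. Pass
#' your own matrix to the generators to break that link.
#'
#' @param nc_observed Number of observed (mixed) channels.
#' @param n_sources Number of latent sources.
#' @return `nc_observed x n_sources` matrix.
#' @export
default_mixing <- function(nc_observed, n_sources) {
  withr::with_seed(424242L, {
    mix <- matrix(runif(nc_observed * n_sources, -1, 1),
                  nc_observed, n_sources)
  })
  mix / sqrt(rowSums(mix^2))
}

synth_segment <- function(regime, dur, mixing, nc_obs, noise_sd) {
  src <- vapply(regime$sources, synth_source, numeric(dur), dur = dur)
  if (is.null(dim(src))) src <- matrix(src, nrow = dur)
  obs <- src %*% t(mixing)
  obs + matrix(rnorm(dur * nc_obs, sd = noise_sd), dur, nc_obs)
}

#' Generate a regime-switching multichannel series with known change-points
#'
#' Draws a sequence of regimes, synthesizes each segment's latent sources,
#' mixes them into `nc - n_noise_channels` observed channels through the
#' mixing matrix, appends pure-noise channels, and adds observation noise.
#' The exact segment boundaries are returned as ground truth (1-based index
#' of the first sample of each new regime). Identical seeds give identical
#' output.
#'
#' Defaults emulate a continuous EMG-like recording: 10 channels driven by
#' 3 latent sources plus 2 pure-noise channels, 5 segments of 1200--2000
#' steps (about 8,000 steps total), observation noise `sd = 0.3` against
#' unit-variance mixed signals (roughly 10 dB SNR).
#'
#' @param regimes List of `lss_regime` objects.
#' @param n_segments Number of segments to concatenate.
#' @param duration_range Integer range of segment durations (steps).
#' @param nc Total channel count (observed plus pure-noise).
#' @param n_noise_channels Pure-noise channels appended after the mixed
#'   block.
#' @param noise_sd Observation-noise standard deviation on the mixed
#'   channels.
#' @param repeat_regimes If `TRUE`, regimes may recur non-adjacently
#'   (requires a temporal constraint downstream); if `FALSE` the segments
#'   are a random permutation of distinct regimes (needs
#'   `n_segments <= length(regimes)`).
#' @param mixing Optional custom mixing matrix
#'   (`(nc - n_noise_channels) x n_sources`); default [default_mixing()].
#' @param seed Integer seed; the only source of randomness.
#' @param nw Optional window length of the intended downstream experiment;
#'   when supplied, segment durations are asserted to be at least `3 * nw`.
#' @return Object of class `lss_sim`: list with `data` (tibble of
#'   channels), `ts` (matrix), `changepoints`, `regime_sequence`,
#'   `durations`, `mixing`, `noise_sd`, `seed`.
#' @export
generate_regime_series <- function(regimes = default_emg_regimes(),
                                   n_segments = length(regimes),
                                   duration_range = c(1200L, 2000L),
                                   nc = 10L, n_noise_channels = 2L,
                                   noise_sd = 0.3, repeat_regimes = FALSE,
                                   mixing = NULL, seed = 1L, nw = NULL) {
  n_sources <- length(regimes[[1]]$sources)
  if (n_sources < 1) abort("regimes need at least one source")
  nc_obs <- nc - n_noise_channels
  if (nc_obs < 1) abort("nc must exceed n_noise_channels")
  if (!repeat_regimes && n_segments > length(regimes)) {
    abort("n_segments > number of regimes requires repeat_regimes = TRUE")
  }
  if (is.null(mixing)) mixing <- default_mixing(nc_obs, n_sources)
  if (!all(dim(mixing) == c(nc_obs, n_sources))) {
    abort(sprintf("mixing must be %d x %d", nc_obs, n_sources))
  }
  withr::with_seed(as.integer(seed), {
    if (repeat_regimes) {
      ids <- integer(n_segments)
      for (s in seq_len(n_segments)) {
        pool <- seq_along(regimes)
        if (s > 1) pool <- setdiff(pool, ids[s - 1])
        ids[s] <- if (length(pool) == 1) pool else sample(pool, 1)
      }
    } else {
      ids <- sample(seq_along(regimes), n_segments)
    }
    dur_pool <- duration_range[1]:duration_range[2]
    durations <- dur_pool[sample.int(length(dur_pool), n_segments,
                                     replace = TRUE)]
    if (!is.null(nw) && any(durations < 3 * nw)) {
      abort(sprintf("segment durations must be >= 3 * nw = %d", 3 * nw))
    }
    segs <- lapply(seq_len(n_segments), function(s) {
      obs <- synth_segment(regimes[[ids[s]]], durations[s], mixing, nc_obs,
                           noise_sd)
      cbind(obs, matrix(rnorm(durations[s] * n_noise_channels),
                        durations[s], n_noise_channels))
    })
  })
  ts <- do.call(rbind, segs)
  colnames(ts) <- sprintf("ch%02d", seq_len(nc))
  cps <- if (n_segments > 1) cumsum(durations)[-n_segments] + 1L else integer(0)
  structure(
    list(data = as_tibble(ts), ts = ts,
         changepoints = as.integer(cps),
         regime_sequence = vapply(regimes[ids], `[[`, character(1), "id"),
         durations = as.integer(durations), mixing = mixing,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "lss_sim"
  )
}

#' @export
print.lss_sim <- function(x, ...) {
  cat(sprintf(
    "<lss_sim> %d steps x %d channels, %d segments (%s), %d change-points, seed %d\n",
    nrow(x$ts), ncol(x$ts), length(x$durations),
    paste(x$regime_sequence, collapse = " "),
    length(x$changepoints), x$seed
  ))
  invisible(x)
}

#' @describeIn generate_regime_series Long-format channel tibble
#'   (`time`, `channel`, `value`).
#' @param x,... Method arguments.
#' @export
tidy.lss_sim <- function(x, ...) {
  df <- dplyr::mutate(x$data, time = dplyr::row_number(), .before = 1)
  tidyr::pivot_longer(df, -"time", names_to = "channel", values_to = "value")
}

#' Generate per-regime training clips (discontinuous training set)
#'
#' Emits `reps` clips per regime with no transitions inside any clip --
#' the construction used to train the window autoencoder when only
#' isolated recordings of each regime exist -- plus their concatenation
#' with the known clip boundaries as an "artificial" evaluation series.
#'
#' @inheritParams generate_regime_series
#' @param reps Clips per regime.
#' @param clip_range Integer range of clip durations (steps).
#' @return List with `clips` (list of channel matrices, one per clip),
#'   `clip_regimes` (labels), and `artificial` (list: `ts`, `changepoints`).
#' @export
generate_training_clips <- function(regimes = default_emg_regimes(),
                                    reps = 2L,
                                    clip_range = c(600L, 1000L),
                                    nc = 10L, n_noise_channels = 2L,
                                    noise_sd = 0.3, mixing = NULL,
                                    seed = 2L) {
  if (reps < 1) abort("reps must be >= 1")
  n_sources <- length(regimes[[1]]$sources)
  nc_obs <- nc - n_noise_channels
  if (nc_obs < 1) abort("nc must exceed n_noise_channels")
  if (is.null(mixing)) mixing <- default_mixing(nc_obs, n_sources)
  withr::with_seed(as.integer(seed), {
    plan <- expand.grid(rep = seq_len(reps), regime = seq_along(regimes))
    clip_pool <- clip_range[1]:clip_range[2]
    clips <- lapply(seq_len(nrow(plan)), function(kk) {
      dur <- clip_pool[sample.int(length(clip_pool), 1)]
      obs <- synth_segment(regimes[[plan$regime[kk]]], dur, mixing, nc_obs,
                           noise_sd)
      out <- cbind(obs, matrix(rnorm(dur * n_noise_channels), dur,
                               n_noise_channels))
      colnames(out) <- sprintf("ch%02d", seq_len(nc))
      out
    })
  })
  lens <- vapply(clips, nrow, integer(1))
  cps <- if (length(clips) > 1) cumsum(lens)[-length(lens)] + 1L else integer(0)
  list(
    clips = clips,
    clip_regimes = vapply(regimes[plan$regime], `[[`, character(1), "id"),
    artificial = list(ts = do.call(rbind, clips), changepoints = as.integer(cps))
  )
}
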