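test_that("the generator is seeded, boundary-exact and shape-correct", {
  a <- generate_regime_series(tiny_regimes(3), n_segments = 3,
                              duration_range = c(100L, 150L), nc = 5,
                              n_noise_channels = 1, seed = 7)
  b <- generate_regime_series(tiny_regimes(3), n_segments = 3,
                              duration_range = c(100L, 150L), nc = 5,
                              n_noise_channels = 1, seed = 7)
  expect_identical(a$ts, b$ts)
  expect_identical(a$changepoints, b$changepoints)

  expect_equal(ncol(a$ts), 5)
  expect_equal(length(a$changepoints), 2)           # segments - 1
  expect_true(all(diff(a$changepoints) > 0))
  expect_equal(nrow(a$ts), sum(a$durations))
  expect_identical(a$changepoints, cumsum(a$durations)[-3] + 1L)

  one <- generate_regime_series(tiny_regimes(1), n_segments = 1,
                                duration_range = c(80L, 90L), nc = 3,
                                n_noise_channels = 1, seed = 3)
  expect_length(one$changepoints, 0)
})

test_that("regime repetition control and duration guidance are enforced", {
  expect_error(generate_regime_series(tiny_regimes(2), n_segments = 4,
                                      duration_range = c(50L, 60L), nc = 3,
                                      n_noise_channels = 1, seed = 1),
               "repeat_regimes")
  rep_sim <- generate_regime_series(tiny_regimes(2), n_segments = 6,
                                    duration_range = c(60L, 80L), nc = 3,
                                    n_noise_channels = 1,
                                    repeat_regimes = TRUE, seed = 5)
  labs <- rep_sim$regime_sequence
  expect_true(all(labs[-1] != labs[-length(labs)]))  # no adjacent repeats
  expect_error(generate_regime_series(tiny_regimes(2), n_segments = 2,
                                      duration_range = c(40L, 50L), nc = 3,
                                      n_noise_channels = 1, seed = 1, nw = 32),
               "3 \\* nw")
})

test_that("training clips: counts, concatenation boundaries, spectral content", {
  clips <- generate_training_clips(tiny_regimes(5), reps = 4,
                                   clip_range = c(150L, 200L), nc = 4,
                                   n_noise_channels = 1, seed = 9)
  expect_length(clips$clips, 20)
  expect_equal(length(clips$artificial$changepoints), 19)
  lens <- vapply(clips$clips, nrow, integer(1))
  expect_identical(clips$artificial$changepoints,
                   cumsum(lens)[-20] + 1L)

  # dominant frequency of a pure-sinusoid regime matches its spec within
  # periodogram resolution
  sin_regime <- list(regime_spec("S", list(src_sinusoid(freq = 0.05))))
  sc <- generate_training_clips(sin_regime, reps = 1,
                                clip_range = c(400L, 400L), nc = 2,
                                n_noise_channels = 1, noise_sd = 0.05,
                                seed = 10)
  ch <- sc$clips[[1]][, 1]
  spec_est <- stats::spec.pgram(ch, plot = FALSE, taper = 0)
  f_hat <- spec_est$freq[which.max(spec_est$spec)]
  expect_lt(abs(f_hat - 0.05), 1 / 400 + 1e-9)
})

test_that("regimes are distinguishable in window space, degrading with noise", {
  # distinguishability in the sense the profile uses it: a window's nearest
  # neighbor inside its own regime is far closer than its nearest neighbor
  # in the other regime; observation noise erodes the gap monotonically
  sin_regimes <- list(
    regime_spec("A", list(src_sinusoid(freq = 0.02))),
    regime_spec("B", list(src_sinusoid(freq = 0.061)))
  )
  nn_gap <- function(noise_sd) {
    sim <- generate_regime_series(sin_regimes, n_segments = 2,
                                  duration_range = c(400L, 400L), nc = 3,
                                  n_noise_channels = 0, noise_sd = noise_sd,
                                  seed = 13)
    w <- latentseg:::window_tensor(sim$ts, 32L, 4L)
    flat <- w; dim(flat) <- c(dim(w)[1], 32 * 3)
    starts <- seq(1, 800 - 32 + 1, by = 4)
    seg <- ifelse(starts + 31 <= 400, 1, ifelse(starts >= 401, 2, NA))
    keep <- !is.na(seg)
    flat <- flat[keep, ]; pos <- starts[keep]; seg <- seg[keep]
    D <- as.matrix(stats::dist(flat))
    diag(D) <- Inf
    D[abs(outer(pos, pos, "-")) < 32] <- Inf   # mask trivial neighbors
    nn_within <- vapply(which(seg == 1), function(j) {
      min(D[j, seg == 1])
    }, numeric(1))
    nn_between <- vapply(which(seg == 1), function(j) {
      min(D[j, seg == 2])
    }, numeric(1))
    mean(nn_between) / mean(nn_within)
  }
  quiet <- nn_gap(0.01)
  mid <- nn_gap(0.3)
  loud <- nn_gap(1.5)
  expect_gte(quiet, 5)
  expect_gt(quiet, mid)
  expect_gt(mid, loud)
})

test_that("the noiseless observed block has rank equal to the source count", {
  sim <- generate_regime_series(tiny_regimes(3), n_segments = 3,
                                duration_range = c(400L, 450L), nc = 7,
                                n_noise_channels = 2, noise_sd = 0,
                                seed = 17)
  observed <- sim$ts[, 1:5]
  expect_equal(qr(observed)$rank, 3)
})
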