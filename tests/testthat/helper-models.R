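# Small fixtures shared across test files; trained models are cached so each
# is fitted once per test run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_regimes <- function(n = 3) default_emg_regimes(n)

tiny_sim <- function(seed = 11, n_segments = 3, dur = c(250L, 350L), nw = 16L) {
  key <- paste("sim", seed, n_segments, dur[1], dur[2])
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_regime_series(
      tiny_regimes(max(3, n_segments)), n_segments = n_segments,
      duration_range = dur, nc = 6L, n_noise_channels = 1L,
      noise_sd = 0.2, seed = seed, nw = nw
    )
  }
  .fixture_cache[[key]]
}

tiny_model <- function(kind = "fully_connected", nc = 6L, nw = 16L,
                       seed = 21) {
  key <- paste("model", kind, nc, nw, seed)
  if (is.null(.fixture_cache[[key]])) {
    clips <- generate_training_clips(
      tiny_regimes(3), reps = 1, clip_range = c(200L, 260L), nc = nc,
      n_noise_channels = 1L, noise_sd = 0.2, seed = seed
    )
    spec <- build_autoencoder(kind, nc, nw)
    .fixture_cache[[key]] <- train_autoencoder(
      clips$clips, spec,
      ae_config(learning_rate = 3e-3, max_epochs = 200, patience = 60,
                train_stride = 4, seed = seed)
    )
  }
  .fixture_cache[[key]]
}
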