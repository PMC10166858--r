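test_that("latent distance profiles are banded plain Euclidean distances", {
  f <- rbind(c(1, 0), c(0, 1), c(3, 4), c(0, 0))
  d <- latent_distance_profile(f, 1, tc = 3, excl = 0)
  expect_equal(d[2], sqrt(2))
  expect_true(is.infinite(d[1]))          # self masked by the exclusion zone
  expect_equal(d[3], sqrt(4 + 16))

  set.seed(501)
  f2 <- matrix(rnorm(60 * 3), 60)
  d2 <- latent_distance_profile(f2, 30, tc = 10, excl = 2)
  for (k in seq_len(60)) {
    if (abs(k - 30) <= 2 || abs(k - 30) > 10) {
      expect_true(is.infinite(d2[k]))
    } else {
      expect_lt(abs(d2[k] - sqrt(sum((f2[k, ] - f2[30, ])^2))), 1e-10)
    }
  }
  expect_error(latent_distance_profile(f2, 0, tc = 5), "query_idx")
  expect_error(latent_distance_profile(f2, 1, tc = 2, excl = 3), "exceed")
})

test_that("full LSMP matches brute force and honors direction", {
  set.seed(502)
  f <- matrix(rnorm(300 * 4), 300)
  # plant an exact duplicate pair inside the band
  f[120, ] <- f[100, ]
  mp <- lsmp_full(f, tc = 50, excl = 3)
  expect_lt(mp$p[100], 1e-10)
  expect_lt(mp$p[120], 1e-10)
  expect_identical(mp$i[100], 120L)
  expect_identical(mp$i[120], 100L)

  for (dir in c("bidirectional", "forward")) {
    mp <- lsmp_full(f, tc = 50, direction = dir, excl = 3)
    expect_profile_equal(mp, oracle_lsmp(f, 50, dir, 3), tol = 1e-10)
  }
  fwd <- lsmp_full(f, tc = 50, direction = "forward", excl = 3)
  fin <- is.finite(fwd$p)
  expect_true(all(fwd$i[fin] > which(fin)))
})

test_that("batched collapse equals the full computation on a parameter grid", {
  set.seed(503)
  f <- matrix(rnorm(500 * 5), 500)
  for (tc in c(20, 50)) {
    for (t_lim in c(150, 200)) {
      for (dir in c("bidirectional", "forward")) {
        full <- lsmp_full(f, tc = tc, direction = dir, excl = 2)
        bat <- batched_collapse(f, t_lim = t_lim, tc = tc, direction = dir,
                                excl = 2)
        fin <- is.finite(full$p)
        expect_identical(is.finite(bat$p), fin)
        expect_lt(max(abs(bat$p[fin] - full$p[fin])), 1e-10)
        expect_identical(bat$i, full$i)
        # memory contract: never more than t_lim x (2 tc + 1) entries
        expect_lte(attr(bat, "max_dist_entries"), t_lim * (2 * tc + 1))
      }
    }
  }
  # single batch degenerates to the full computation
  one <- batched_collapse(f, t_lim = 600, tc = 20, excl = 2)
  full <- lsmp_full(f, tc = 20, excl = 2)
  expect_equal(one$p, full$p)
  expect_error(batched_collapse(f, t_lim = 40, tc = 20, excl = 2),
               "exceed 2 \\* tc")
})

test_that("streaming equals offline for any chunking, in both directions", {
  set.seed(504)
  f <- matrix(rnorm(400 * 4), 400)
  for (dir in c("bidirectional", "forward")) {
    full <- lsmp_full(f, tc = 40, direction = dir, excl = 2)
    for (chunk in c(37, 101, 399)) {
      st <- lsmp_online_init(f[1:50, ], tc = 40, direction = dir, excl = 2)
      start <- 51L
      while (start <= 400) {
        end <- min(start + chunk - 1L, 400L)
        st <- lsmp_online_append(st, f[start:end, , drop = FALSE])
        start <- end + 1L
      }
      fin <- is.finite(full$p)
      expect_identical(is.finite(st$p), fin)
      expect_lt(max(abs(st$p[fin] - full$p[fin])), 1e-10)
      expect_identical(st$i, full$i)
    }
  }
})

test_that("streaming appends are monotone improvements and validate input", {
  set.seed(505)
  f <- matrix(rnorm(200 * 3), 200)
  st <- lsmp_online_init(f[1:150, ], tc = 30, direction = "forward", excl = 1)
  before <- st$p
  st2 <- lsmp_online_append(st, f[151:200, ])
  expect_true(all(st2$p[1:150] <= before + 1e-12))

  # appending zero rows changes nothing
  expect_identical(lsmp_online_append(st, f[0, , drop = FALSE]), st)
  expect_error(lsmp_online_append(st, matrix(0, 2, 5)), "latent_dim")
})

test_that("adjacent-window latent distances flag a sharp regime transition", {
  model <- tiny_model()
  # constant series: flat distance curve, no change-points
  const <- matrix(0.5, 200, 6)
  expect_length(lfmd_changepoints(const, model), 0)

  sim2 <- generate_regime_series(tiny_regimes(2), n_segments = 2,
                                 duration_range = c(300L, 320L), nc = 6,
                                 n_noise_channels = 1, noise_sd = 0.1,
                                 seed = 31)
  cp <- lfmd_changepoints(sim2$ts, model, overlap = 8)
  dcurve <- attr(cp, "distance_curve")
  n_windows <- floor((nrow(sim2$ts) - 16) / 8) + 1
  expect_length(dcurve, n_windows - 1)
  expect_gte(length(cp), 1)
  expect_lte(min(abs(cp - sim2$changepoints[1])), 16)
  expect_error(lfmd_changepoints(sim2$ts, model, overlap = 16), "overlap")
})
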