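test_that("arc counting matches the strict-interior crossing rule", {
  expect_equal(count_arcs(c(3L, 4L, 1L, 2L)), c(0, 2, 2, 0))
  # adjacent arcs have no strict interior
  expect_equal(count_arcs(c(2L, 1L, 4L, 3L)), rep(0, 4))
  # NA (no partner) entries contribute nothing
  expect_equal(count_arcs(c(3L, NA, 1L)), c(0, 2, 0))
  expect_error(count_arcs(c(5L, 1L)), "out of range")
})

test_that("arc counting equals the per-arc brute force; crossings sum to span-1", {
  set.seed(301)
  for (rep in 1:20) {
    L <- sample(20:120, 1)
    i <- latentseg:::sample_random_partners(L, "bidirectional", Inf)
    ac <- count_arcs(i)
    expect_equal(ac, oracle_count_arcs(i))
    spans <- abs(i - seq_len(L))
    expect_equal(sum(ac), sum(pmax(spans - 1, 0)))
  }
})

test_that("analytic idealized curve has the parabola geometry", {
  iac <- idealized_arc_curve(101)
  expect_equal(iac$raw[51], 50)             # midpoint height = half the length
  expect_equal(iac$raw[1], 0)               # no crossings at the edge
  expect_equal(iac$iac[1], 1)               # ... clamped to 1 as a divisor
  expect_equal(iac$mode, "bidirectional_analytic")
  expect_lte(max(iac$iac), 101 / 2)
})

test_that("simulated idealized curve agrees with the analytic parabola", {
  # Monte-Carlo estimate with the same partner sampler, compared to the
  # closed form within 3 standard errors pointwise
  ana <- idealized_arc_curve(200)$raw
  acc <- numeric(200); acc2 <- numeric(200)
  withr::with_seed(17, {
    for (t in 1:2000) {
      ac <- count_arcs(latentseg:::sample_random_partners(200, "bidirectional", Inf))
      acc <- acc + ac; acc2 <- acc2 + ac^2
    }
  })
  raw <- acc / 2000
  se <- sqrt(pmax(acc2 / 2000 - raw^2, 0) / 2000)
  expect_true(all(abs(raw - ana) <= 3 * se + 1e-9))
})

test_that("forward idealized curve is right-skewed and deterministic by seed", {
  a <- idealized_arc_curve(150, direction = "forward", tc = Inf,
                           n_trials = 300, seed = 3)
  b <- idealized_arc_curve(150, direction = "forward", tc = Inf,
                           n_trials = 300, seed = 3)
  expect_identical(a$raw, b$raw)
  expect_equal(a$mode, "simulated")
  # unconstrained forward arcs pile up over the later positions
  expect_gt(which.max(a$raw), 75)

  tcc <- idealized_arc_curve(150, direction = "forward", tc = 30,
                             n_trials = 300, seed = 3)
  expect_equal(tcc$mode, "simulated")
  expect_true(all(tcc$raw <= 31))           # crossings bounded by the band
})

test_that("corrected arc curve is a clamped ratio with forced edges", {
  iac <- idealized_arc_curve(200)
  cac1 <- corrected_arc_curve(iac$raw, iac)
  expect_true(all(cac1 == 1))               # ac = iac everywhere

  interior <- iac$raw >= 25                 # default evidence floor
  expect_gt(sum(interior), 150)
  cac0 <- corrected_arc_curve(numeric(200), iac)
  expect_true(all(cac0[interior] == 0))
  expect_true(all(cac0[!interior] == 1))    # edges: no evidence

  # a stricter floor widens the protected margin
  strict <- corrected_arc_curve(numeric(200), iac, min_expected_arcs = 60)
  expect_gt(sum(strict == 1), sum(cac0 == 1))

  over <- corrected_arc_curve(iac$raw * 3, iac)
  expect_true(all(over <= 1))
  expect_error(corrected_arc_curve(numeric(10), iac), "length")
})

test_that("curve from a profile stays in [0,1] and records the iac mode", {
  set.seed(302)
  x <- matrix(rnorm(300), ncol = 1)
  mp <- stamp(x, 8)
  cac <- cac_from_profile(mp, seed = 1)
  expect_true(all(cac >= 0 & cac <= 1))
  expect_equal(attr(cac, "iac_mode"), "bidirectional_analytic")

  fw <- stamp(x, 8, tc = 50, direction = "forward")
  cfw <- cac_from_profile(fw, n_trials = 200, seed = 1)
  expect_true(all(cfw >= 0 & cfw <= 1))
  expect_equal(attr(cfw, "iac_mode"), "simulated")
})

test_that("a structureless index vector calibrates near 1 in the interior", {
  withr::with_seed(303, {
    i <- latentseg:::sample_random_partners(500, "bidirectional", Inf)
  })
  cac <- corrected_arc_curve(count_arcs(i), idealized_arc_curve(500))
  central <- 126:375
  expect_gte(mean(cac[central]), 0.8)
})
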