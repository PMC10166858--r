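test_that("REA picks valley minima under iterative exclusion masking", {
  curve <- rep(1, 100); curve[40] <- 0
  expect_identical(rea(curve, k = 1, excl_width = 10), 40L)

  # two valleys 10 apart with excl_width 15: the deeper one wins, the next
  # pick must come from outside its zone
  c2 <- rep(1, 100); c2[30] <- 0.1; c2[40] <- 0.2; c2[70] <- 0.3
  expect_identical(rea(c2, k = 2, excl_width = 15), c(30L, 70L))

  # three isolated valleys, k = 3: all three in sorted order
  c3 <- rep(1, 200); c3[50] <- 0.3; c3[120] <- 0.1; c3[180] <- 0.2
  expect_identical(rea(c3, k = 3, excl_width = 20), c(50L, 120L, 180L))

  # exhausted curve warns and returns what it found
  expect_warning(res <- rea(c(0.5, 0.4, 0.6), k = 3, excl_width = 5),
                 "extractable")
  expect_identical(res, 2L)
})

test_that("local scaling matches direct rolling statistics", {
  expect_equal(scale_cac(rep(0.7, 50), 5)$values, rep(0, 50))

  # saturated window: equals the global (population) z-score
  set.seed(601)
  x <- runif(40)
  sat <- scale_cac(x, local_window = 100, scaling_mode = "centered")
  glob <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(sat$values, glob, tolerance = 1e-10)

  # centered mode, direct per-position loop
  x2 <- runif(120)
  w <- 25
  sc <- scale_cac(x2, w, "centered")
  for (j in c(1, 13, 60, 108, 120)) {
    win <- x2[max(1, j - w):min(120, j + w)]
    mu <- mean(win); s <- sqrt(mean((win - mu)^2))
    expect_lt(abs(sc$values[j] - (x2[j] - mu) / s), 1e-10)
  }

  # trailing mode uses only the past
  tr <- scale_cac(x2, w, "trailing")
  for (j in c(1, 30, 120)) {
    win <- x2[max(1, j - 2 * w):j]
    mu <- mean(win); s <- sqrt(mean((win - mu)^2))
    ref <- if (s < 1e-12) 0 else (x2[j] - mu) / s
    expect_lt(abs(tr$values[j] - ref), 1e-10)
  }
})

test_that("LREA prefers locally sharp valleys over globally low plateaus", {
  # a flat globally-low plateau vs a locally dramatic narrow valley
  curve <- rep(0.8, 100)
  curve[20:40] <- 0.2     # plateau: constant, locally unremarkable
  curve[70] <- 0.5        # sharp dip against the 0.8 baseline
  expect_identical(rea(curve, k = 1, excl_width = 8), 20L)   # global min
  expect_identical(lrea(curve, k = 1, local_window = 8, excl_width = 8), 70L)

  # single-valley scaled curve
  c1 <- rep(0.9, 60); c1[25] <- 0.1
  expect_identical(lrea(c1, k = 1, local_window = 10, excl_width = 5), 25L)
})

test_that("LREA tends to REA as the window saturates", {
  set.seed(602)
  curve <- runif(150)
  k <- 4; ew <- 10
  sat <- lrea(curve, k, local_window = 10 * length(curve), excl_width = ew)
  glob <- (curve - mean(curve)) / sqrt(mean((curve - mean(curve))^2))
  expect_identical(sat, rea(glob, k, ew))
  expect_identical(sat, rea(curve, k, ew))  # monotone transform, same order
})

test_that("LTEA thresholding extracts valley minima without a known count", {
  # never below threshold: empty result is valid
  expect_length(ltea(rep(0.9, 200), local_window = 20, excl_width = 10), 0)

  # one contiguous sub-threshold run with its minimum at 812
  curve <- rep(0.9, 1000)
  dip <- 800:824
  curve[dip] <- 0.9 - 0.5 * cos((dip - 812) / 13 * pi / 2)^2
  res <- ltea(curve, local_window = 25, excl_width = 50,
              scaling_mode = "centered")
  expect_identical(res, 812L)
})

test_that("LTEA invariants hold under fuzzing", {
  set.seed(603)
  for (rep in 1:15) {
    L <- sample(200:600, 1)
    curve <- runif(L)
    w <- sample(10:40, 1)
    ew <- sample(5:60, 1)
    res <- ltea(curve, local_window = w, excl_width = ew)
    s <- scale_cac(curve, w, "trailing")$values
    if (length(res) > 0) {
      expect_true(all(s[res] <= -1))
      if (length(res) > 1) expect_true(all(diff(res) > ew))
    }
  }
})

test_that("LTEA output is local: shuffling a distant block leaves far minima intact", {
  set.seed(604)
  curve <- runif(600)
  w <- 20; ew <- 30
  res <- ltea(curve, local_window = w, excl_width = ew)
  block <- 450:600
  shuffled <- curve
  shuffled[block] <- sample(curve[block])
  res2 <- ltea(shuffled, local_window = w, excl_width = ew)
  influence <- min(block) - (2 * w + ew + 1)
  expect_identical(res[res < influence], res2[res2 < influence])
})
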