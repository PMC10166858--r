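# Independent brute-force oracles. These deliberately avoid the package's
# fast paths: windows are sliced directly, z-normalization uses explicit
# moments, and nearest neighbors come from a full stats::dist() matrix with
# masks applied row by row.

oracle_znorm_windows <- function(xm, m) {
  count <- nrow(xm) - m + 1
  z <- NULL
  for (ch in seq_len(ncol(xm))) {
    w <- t(vapply(seq_len(count), function(j) xm[j:(j + m - 1), ch],
                  numeric(m)))
    mu <- rowMeans(w)
    s <- sqrt(rowMeans((w - mu)^2))
    wz <- (w - mu) / ifelse(s < 1e-12, 1, s)
    wz[s < 1e-12, ] <- 0
    z <- cbind(z, wz)
  }
  z
}

oracle_stamp <- function(xm, m, tc = Inf, direction = "bidirectional",
                         excl = ceiling(m / 4)) {
  z <- oracle_znorm_windows(xm, m)
  count <- nrow(z)
  D <- as.matrix(stats::dist(z))
  ks <- seq_len(count)
  for (j in ks) {
    D[j, abs(ks - j) <= excl] <- Inf
    if (is.finite(tc)) D[j, abs(ks - j) > tc] <- Inf
    if (direction == "forward") D[j, ks <= j + excl] <- Inf
  }
  p <- unname(apply(D, 1, min))
  i <- as.integer(unname(apply(D, 1, which.min)))
  i[!is.finite(p)] <- NA_integer_
  list(p = p, i = i)
}

oracle_lsmp <- function(f, tc, direction = "bidirectional", excl = 0L) {
  N <- nrow(f)
  D <- as.matrix(stats::dist(f))
  ks <- seq_len(N)
  for (j in ks) {
    D[j, abs(ks - j) <= excl] <- Inf
    D[j, abs(ks - j) > tc] <- Inf
    if (direction == "forward") D[j, ks <= j + excl] <- Inf
  }
  p <- unname(apply(D, 1, min))
  i <- as.integer(unname(apply(D, 1, which.min)))
  i[!is.finite(p)] <- NA_integer_
  list(p = p, i = i)
}

oracle_count_arcs <- function(i) {
  L <- length(i)
  ac <- numeric(L)
  for (j in seq_along(i)) {
    if (is.na(i[j])) next
    a <- min(j, i[j]); b <- max(j, i[j])
    if (b - a >= 2) ac[(a + 1):(b - 1)] <- ac[(a + 1):(b - 1)] + 1
  }
  ac
}

expect_profile_equal <- function(mp, oracle, tol = 1e-8) {
  fin <- is.finite(oracle$p)
  expect_identical(is.finite(mp$p), fin)
  expect_lt(max(abs(mp$p[fin] - oracle$p[fin]), 0), tol)
  expect_identical(mp$i, oracle$i)
}
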