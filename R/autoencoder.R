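#' Autoencoder architecture specification
#'
#' Builds the layer plan for one of the two window-autoencoder architectures
#' used by the latent-space segmentation pipeline. Both take a multichannel
#' window of `nw` time steps by `nc` channels and compress it through an
#' information bottleneck:
#'
#' * `"fully_connected"`: the window is flattened to `d = nc * nw` inputs;
#'   the encoder halves the width twice (`d -> d/2 -> d/4`) and projects to a
#'   latent of `max(1, round(0.1 * d))` units, sigmoid activations
#'   throughout. The decoder mirrors the encoder using the *transposed
#'   encoder weights* (tied), with its own biases and a linear output.
#' * `"convolutional"`: two strided 1-d convolutions
#'   (`nc -> 2nc -> 4nc` channels, kernel 3, stride 2, padding 1) halve the
#'   temporal length twice, the result is flattened back to `nc * nw`
#'   features, and three fully connected layers
#'   (`d -> d/2 -> d/4 -> round(d/6)`) reach the latent, all ReLU. The
#'   decoder mirrors the shapes with independently learned transposed
#'   fully connected and transposed convolution layers; the final
#'   reconstruction is linear.
#'
#' The bottleneck ratios (`latent/d` of 0.1 and 1/6) are the two feature
#' sizes of the reference architectures.
#'
#' @param kind `"fully_connected"` or `"convolutional"`.
#' @param nc Channel count, `>= 1`.
#' @param nw Window (subsequence) length. The convolutional kind needs
#'   `nw` divisible by 4 (two stride-2 layers); the fully connected kind
#'   needs `nc * nw >= 10` so the 0.1 ratio yields a latent unit.
#' @return Object of class `lss_ae_spec`.
#' @export
#' @examples
#' build_autoencoder("fully_connected", nc = 9, nw = 50)  # latent 45
#' build_autoencoder("convolutional", nc = 10, nw = 24)   # latent 40
build_autoencoder <- function(kind = c("fully_connected", "convolutional"),
                              nc, nw) {
  kind <- match.arg(kind)
  nc <- as.integer(nc)
  nw <- as.integer(nw)
  if (nc < 1 || nw < 2) abort("need nc >= 1 and nw >= 2")
  d <- nc * nw
  if (kind == "convolutional") {
    if (nw %% 4L != 0L) {
      abort(sprintf(
        "convolutional autoencoder needs nw divisible by 4 (two stride-2 layers); got nw = %d. Pad the window or choose nw = %d or %d.",
        nw, 4L * (nw %/% 4L), 4L * (nw %/% 4L + 1L)
      ))
    }
    latent <- max(1L, as.integer(round(d / 6)))
    sizes <- c(d = d, h1 = d %/% 2L, h2 = d %/% 4L, latent = latent)
  } else {
    if (d < 10L) {
      abort(sprintf(
        "fully connected autoencoder needs nc * nw >= 10 for a non-empty latent; got %d x %d = %d. Increase nw.",
        nc, nw, d
      ))
    }
    latent <- max(1L, as.integer(round(0.1 * d)))
    sizes <- c(d = d, h1 = d %/% 2L, h2 = (d %/% 2L) %/% 2L, latent = latent)
  }
  structure(
    list(kind = kind, nc = nc, nw = nw, d = d, latent_dim = latent,
         sizes = sizes,
         tied_decoder = kind == "fully_connected"),
    class = "lss_ae_spec"
  )
}

#' @export
print.lss_ae_spec <- function(x, ...) {
  cat(sprintf(
    "<lss_ae_spec> %s: %d ch x %d steps -> latent %d (ratio %.3f), %s decoder\n",
    x$kind, x$nc, x$nw, x$latent_dim, x$latent_dim / x$d,
    if (x$tied_decoder) "tied" else "mirrored"
  ))
  invisible(x)
}

#' Total number of trainable parameters of an architecture
#'
#' @param spec An `lss_ae_spec`.
#' @return Integer parameter count (weights plus biases, counting tied
#'   weights once).
#' @export
ae_param_count <- function(spec) {
  s <- spec$sizes
  if (spec$kind == "fully_connected") {
    # tied weights counted once; encoder and decoder biases separate
    s[["d"]] * s[["h1"]] + s[["h1"]] * s[["h2"]] + s[["h2"]] * s[["latent"]] +
      (s[["h1"]] + s[["h2"]] + s[["latent"]]) +
      (s[["h2"]] + s[["h1"]] + s[["d"]])
  } else {
    nc <- spec$nc
    3L * nc * 2L * nc + 2L * nc +          # conv1 + bias
      3L * 2L * nc * 4L * nc + 4L * nc +   # conv2 + bias
      s[["d"]] * s[["h1"]] + s[["h1"]] +
      s[["h1"]] * s[["h2"]] + s[["h2"]] +
      s[["h2"]] * s[["latent"]] + s[["latent"]] +
      s[["latent"]] * s[["h2"]] + s[["h2"]] +
      s[["h2"]] * s[["h1"]] + s[["h1"]] +
      s[["h1"]] * s[["d"]] + s[["d"]] +
      3L * 2L * nc * 4L * nc + 2L * nc +   # tconv (conv2 geometry) + bias
      3L * nc * 2L * nc + nc               # tconv (conv1 geometry) + bias
  }
}

#' Training configuration for the window autoencoder
#'
#' Defaults follow common practice for small Adam-trained models; all are
#' exposed because the reference pipeline grid-searches several of them.
#' `val_fraction = 0.2` holds out 20% of the training windows for early
#' stopping. `train_stride` subsamples the training windows (stride-1
#' windows overlap in `nw - 1` samples and are heavily redundant; a larger
#' stride decorrelates them and speeds training without hurting the
#' representation). `scaler` selects the per-channel scaling fitted on the
#' training data only.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs Upper bound on training epochs.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of windows held out for validation, in (0,1).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param train_stride Stride between training windows (encoding is always
#'   stride 1 regardless).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param scaler One of `"standard"`, `"minmax"`, `"robust"`, `"maxabs"`,
#'   `"none"`.
#' @return List of class `lss_ae_config`.
#' @export
ae_config <- function(learning_rate = 1e-3, max_epochs = 200, batch_size = 64,
                      val_fraction = 0.2, seed = 1L, train_stride = 1L,
                      patience = 20, scaler = "standard") {
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort("val_fraction must be in (0, 1)")
  }
  scaler <- match.arg(scaler, c("standard", "minmax", "robust", "maxabs", "none"))
  structure(
    list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         seed = as.integer(seed), train_stride = as.integer(train_stride),
         patience = as.integer(patience), scaler = scaler),
    class = "lss_ae_config"
  )
}

## ---- channel scalers -------------------------------------------------------

fit_scaler <- function(xm, method) {
  center <- switch(method,
    none = rep(0, ncol(xm)),
    standard = colMeans(xm),
    minmax = apply(xm, 2, min),
    robust = apply(xm, 2, stats::median),
    maxabs = rep(0, ncol(xm))
  )
  scale <- switch(method,
    none = rep(1, ncol(xm)),
    standard = apply(xm, 2, stats::sd),
    minmax = apply(xm, 2, max) - apply(xm, 2, min),
    robust = apply(xm, 2, stats::IQR),
    maxabs = apply(xm, 2, function(v) max(abs(v)))
  )
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(method = method, center = center, scale = scale)
}

apply_scaler <- function(xm, scaler) {
  sweep(sweep(xm, 2, scaler$center), 2, scaler$scale, "/")
}

## ---- 1-d convolution primitives -------------------------------------------
## Arrays are (batch, length, channels). A "geometry" describes a strided
## convolution L_in -> L_out; the transposed convolution is its adjoint and
## reuses the same geometry in the opposite direction.

conv_geom <- function(L_in, C_in, C_out, k = 3L, s = 2L, p = 1L) {
  L_out <- (L_in + 2L * p - k) %/% s + 1L
  # idx[kk, t] = position in the padded input feeding output step t, tap kk
  idx <- outer(seq_len(k), s * (seq_len(L_out) - 1L), "+")
  list(L_in = L_in, L_out = L_out, C_in = C_in, C_out = C_out,
       k = k, s = s, p = p, Lp = L_in + 2L * p, idx = idx)
}

pad_len <- function(X, g) {
  B <- dim(X)[1]
  Xp <- array(0, c(B, g$Lp, g$C_in))
  Xp[, g$p + seq_len(g$L_in), ] <- X
  Xp
}

im2col <- function(X, g) {
  B <- dim(X)[1]
  Xp <- pad_len(X, g)
  Xg <- Xp[, as.vector(g$idx), , drop = FALSE]   # (B, k*L_out, C_in), kk fastest
  dim(Xg) <- c(B, g$k, g$L_out, g$C_in)
  Xg <- aperm(Xg, c(1, 3, 2, 4))                 # (B, L_out, k, C_in)
  dim(Xg) <- c(B * g$L_out, g$k * g$C_in)
  Xg
}

col2im <- function(Gcol, g, B) {
  dim(Gcol) <- c(B, g$L_out, g$k, g$C_in)
  Gp <- array(0, c(B, g$Lp, g$C_in))
  for (kk in seq_len(g$k)) {
    pos <- g$idx[kk, ]
    Gp[, pos, ] <- Gp[, pos, ] + Gcol[, , kk, ]
  }
  Gp[, g$p + seq_len(g$L_in), , drop = FALSE]
}

conv_fwd <- function(X, W, b, g) {
  B <- dim(X)[1]
  Xcol <- im2col(X, g)
  Y <- Xcol %*% W
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(B, g$L_out, g$C_out)
  list(Y = Y, Xcol = Xcol)
}

conv_bwd <- function(gY, Xcol, W, g) {
  B <- dim(gY)[1]
  gYm <- gY
  dim(gYm) <- c(B * g$L_out, g$C_out)
  list(
    dW = crossprod(Xcol, gYm),
    db = colSums(gYm),
    gX = col2im(gYm %*% t(W), g, B)
  )
}

# transposed convolution: maps (B, L_out, C_out) -> (B, L_in, C_in)
tconv_fwd <- function(X, W, b, g) {
  B <- dim(X)[1]
  Xm <- X
  dim(Xm) <- c(B * g$L_out, g$C_out)
  Y <- col2im(Xm %*% t(W), g, B)
  Y <- sweep(Y, 3, b, "+")
  list(Y = Y, Xm = Xm)
}

tconv_bwd <- function(gY, Xm, W, g) {
  B <- dim(gY)[1]
  gYcol <- im2col(gY, g)           # (B*L_out, k*C_in)
  gX <- gYcol %*% W                # (B*L_out, C_out)
  dim(gX) <- c(B, g$L_out, g$C_out)
  list(
    dW = crossprod(gYcol, Xm),
    db = apply(gY, 3, sum),
    gX = gX
  )
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(n_in, n_out, nr, nc_) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(runif(nr * nc_, -a, a), nr, nc_)
}

ae_init_params <- function(spec) {
  s <- spec$sizes
  if (spec$kind == "fully_connected") {
    list(
      W1 = glorot(s[["d"]], s[["h1"]], s[["d"]], s[["h1"]]),
      b1 = numeric(s[["h1"]]),
      W2 = glorot(s[["h1"]], s[["h2"]], s[["h1"]], s[["h2"]]),
      b2 = numeric(s[["h2"]]),
      W3 = glorot(s[["h2"]], s[["latent"]], s[["h2"]], s[["latent"]]),
      b3 = numeric(s[["latent"]]),
      c3 = numeric(s[["h2"]]),
      c2 = numeric(s[["h1"]]),
      c1 = numeric(s[["d"]])
    )
  } else {
    nc <- spec$nc
    g1 <- conv_geom(spec$nw, nc, 2L * nc)
    g2 <- conv_geom(g1$L_out, 2L * nc, 4L * nc)
    fan_k1 <- 3L * nc
    fan_k2 <- 3L * 2L * nc
    list(
      K1 = glorot(fan_k1, 2L * nc, 3L * nc, 2L * nc),
      bK1 = numeric(2L * nc),
      K2 = glorot(fan_k2, 4L * nc, 3L * 2L * nc, 4L * nc),
      bK2 = numeric(4L * nc),
      F1 = glorot(s[["d"]], s[["h1"]], s[["d"]], s[["h1"]]),
      bF1 = numeric(s[["h1"]]),
      F2 = glorot(s[["h1"]], s[["h2"]], s[["h1"]], s[["h2"]]),
      bF2 = numeric(s[["h2"]]),
      F3 = glorot(s[["h2"]], s[["latent"]], s[["h2"]], s[["latent"]]),
      bF3 = numeric(s[["latent"]]),
      G3 = glorot(s[["latent"]], s[["h2"]], s[["latent"]], s[["h2"]]),
      cG3 = numeric(s[["h2"]]),
      G2 = glorot(s[["h2"]], s[["h1"]], s[["h2"]], s[["h1"]]),
      cG2 = numeric(s[["h1"]]),
      G1 = glorot(s[["h1"]], s[["d"]], s[["h1"]], s[["d"]]),
      cG1 = numeric(s[["d"]]),
      T2 = glorot(fan_k2, 4L * nc, 3L * 2L * nc, 4L * nc),
      bT2 = numeric(2L * nc),
      T1 = glorot(fan_k1, 2L * nc, 3L * nc, 2L * nc),
      bT1 = numeric(nc)
    )
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) (x > 0) * x

## ---- forward / backward ----------------------------------------------------
## X is the window tensor (B, nw, nc); the FC path flattens it column-major
## (time fastest within channel).

ae_forward_fc <- function(spec, p, X) {
  B <- dim(X)[1]
  Xf <- X; dim(Xf) <- c(B, spec$d)
  a1 <- sigmoid(sweep(Xf %*% p$W1, 2, p$b1, "+"))
  a2 <- sigmoid(sweep(a1 %*% p$W2, 2, p$b2, "+"))
  z  <- sigmoid(sweep(a2 %*% p$W3, 2, p$b3, "+"))
  d3 <- sigmoid(sweep(z %*% t(p$W3), 2, p$c3, "+"))
  d2 <- sigmoid(sweep(d3 %*% t(p$W2), 2, p$c2, "+"))
  xhat <- sweep(d2 %*% t(p$W1), 2, p$c1, "+")
  list(xhat = xhat, z = z, cache = list(Xf = Xf, a1 = a1, a2 = a2,
                                        d3 = d3, d2 = d2))
}

ae_grad_fc <- function(spec, p, X) {
  B <- dim(X)[1]
  fw <- ae_forward_fc(spec, p, X)
  ca <- fw$cache
  loss <- mean((fw$xhat - ca$Xf)^2)
  g <- 2 * (fw$xhat - ca$Xf) / length(ca$Xf)
  gr <- list()
  gr$c1 <- colSums(g)
  dW1 <- crossprod(g, ca$d2)                      # decoder use of W1
  gd2 <- (g %*% p$W1) * ca$d2 * (1 - ca$d2)
  gr$c2 <- colSums(gd2)
  dW2 <- crossprod(gd2, ca$d3)
  gd3 <- (gd2 %*% p$W2) * ca$d3 * (1 - ca$d3)
  gr$c3 <- colSums(gd3)
  dW3 <- crossprod(gd3, fw$z)
  gz <- (gd3 %*% p$W3) * fw$z * (1 - fw$z)
  gr$b3 <- colSums(gz)
  dW3 <- dW3 + crossprod(ca$a2, gz)               # encoder use of W3
  ga2 <- (gz %*% t(p$W3)) * ca$a2 * (1 - ca$a2)
  gr$b2 <- colSums(ga2)
  dW2 <- dW2 + crossprod(ca$a1, ga2)
  ga1 <- (ga2 %*% t(p$W2)) * ca$a1 * (1 - ca$a1)
  gr$b1 <- colSums(ga1)
  dW1 <- dW1 + crossprod(ca$Xf, ga1)
  gr$W1 <- dW1; gr$W2 <- dW2; gr$W3 <- dW3
  list(loss = loss, grads = gr)
}

conv_geoms <- function(spec) {
  g1 <- conv_geom(spec$nw, spec$nc, 2L * spec$nc)
  g2 <- conv_geom(g1$L_out, 2L * spec$nc, 4L * spec$nc)
  list(g1 = g1, g2 = g2)
}

ae_forward_conv <- function(spec, p, X, geoms = conv_geoms(spec)) {
  B <- dim(X)[1]
  g1 <- geoms$g1; g2 <- geoms$g2
  c1 <- conv_fwd(X, p$K1, p$bK1, g1)
  h1 <- relu(c1$Y)
  c2 <- conv_fwd(h1, p$K2, p$bK2, g2)
  h2 <- relu(c2$Y)
  flat <- h2; dim(flat) <- c(B, spec$d)
  f1 <- relu(sweep(flat %*% p$F1, 2, p$bF1, "+"))
  f2 <- relu(sweep(f1 %*% p$F2, 2, p$bF2, "+"))
  z  <- relu(sweep(f2 %*% p$F3, 2, p$bF3, "+"))
  u3 <- relu(sweep(z %*% p$G3, 2, p$cG3, "+"))
  u2 <- relu(sweep(u3 %*% p$G2, 2, p$cG2, "+"))
  u1 <- relu(sweep(u2 %*% p$G1, 2, p$cG1, "+"))
  ur <- u1; dim(ur) <- c(B, g2$L_out, g2$C_out)
  t2 <- tconv_fwd(ur, p$T2, p$bT2, g2)
  v2 <- relu(t2$Y)
  t1 <- tconv_fwd(v2, p$T1, p$bT1, g1)
  xhat <- t1$Y                                    # linear output
  list(xhat = xhat, z = z,
       cache = list(c1 = c1, h1 = h1, c2 = c2, h2 = h2, flat = flat,
                    f1 = f1, f2 = f2, u3 = u3, u2 = u2, u1 = u1, ur = ur,
                    t2 = t2, v2 = v2, t1 = t1, geoms = geoms))
}

ae_grad_conv <- function(spec, p, X, geoms = conv_geoms(spec)) {
  B <- dim(X)[1]
  fw <- ae_forward_conv(spec, p, X, geoms)
  ca <- fw$cache
  g1 <- geoms$g1; g2 <- geoms$g2
  loss <- mean((fw$xhat - X)^2)
  g <- 2 * (fw$xhat - X) / length(X)
  gr <- list()
  bt1 <- tconv_bwd(g, ca$t1$Xm, p$T1, g1)
  gr$T1 <- bt1$dW; gr$bT1 <- bt1$db
  gv2 <- bt1$gX * (ca$t2$Y > 0)
  bt2 <- tconv_bwd(gv2, ca$t2$Xm, p$T2, g2)
  gr$T2 <- bt2$dW; gr$bT2 <- bt2$db
  gu1 <- bt2$gX; dim(gu1) <- c(B, spec$d)
  gu1 <- gu1 * (ca$u1 > 0)
  gr$cG1 <- colSums(gu1); gr$G1 <- crossprod(ca$u2, gu1)
  gu2 <- (gu1 %*% t(p$G1)) * (ca$u2 > 0)
  gr$cG2 <- colSums(gu2); gr$G2 <- crossprod(ca$u3, gu2)
  gu3 <- (gu2 %*% t(p$G2)) * (ca$u3 > 0)
  gr$cG3 <- colSums(gu3); gr$G3 <- crossprod(fw$z, gu3)
  gz <- (gu3 %*% t(p$G3)) * (fw$z > 0)
  gr$bF3 <- colSums(gz); gr$F3 <- crossprod(ca$f2, gz)
  gf2 <- (gz %*% t(p$F3)) * (ca$f2 > 0)
  gr$bF2 <- colSums(gf2); gr$F2 <- crossprod(ca$f1, gf2)
  gf1 <- (gf2 %*% t(p$F2)) * (ca$f1 > 0)
  gr$bF1 <- colSums(gf1); gr$F1 <- crossprod(ca$flat, gf1)
  gflat <- gf1 %*% t(p$F1)
  dim(gflat) <- c(B, g2$L_out, g2$C_out)
  gh2 <- gflat * (ca$c2$Y > 0)
  bc2 <- conv_bwd(gh2, ca$c2$Xcol, p$K2, g2)
  gr$K2 <- bc2$dW; gr$bK2 <- bc2$db
  gh1 <- bc2$gX * (ca$c1$Y > 0)
  bc1 <- conv_bwd(gh1, ca$c1$Xcol, p$K1, g1)
  gr$K1 <- bc1$dW; gr$bK1 <- bc1$db
  list(loss = loss, grads = gr)
}

ae_forward <- function(spec, p, X, geoms = NULL) {
  if (spec$kind == "fully_connected") ae_forward_fc(spec, p, X)
  else ae_forward_conv(spec, p, X, geoms %||% conv_geoms(spec))
}

ae_grad <- function(spec, p, X, geoms = NULL) {
  if (spec$kind == "fully_connected") ae_grad_fc(spec, p, X)
  else ae_grad_conv(spec, p, X, geoms %||% conv_geoms(spec))
}

ae_encode_batch <- function(spec, p, X) {
  B <- dim(X)[1]
  if (spec$kind == "fully_connected") {
    Xf <- X; dim(Xf) <- c(B, spec$d)
    a1 <- sigmoid(sweep(Xf %*% p$W1, 2, p$b1, "+"))
    a2 <- sigmoid(sweep(a1 %*% p$W2, 2, p$b2, "+"))
    sigmoid(sweep(a2 %*% p$W3, 2, p$b3, "+"))
  } else {
    geoms <- conv_geoms(spec)
    h1 <- relu(conv_fwd(X, p$K1, p$bK1, geoms$g1)$Y)
    h2 <- relu(conv_fwd(h1, p$K2, p$bK2, geoms$g2)$Y)
    flat <- h2; dim(flat) <- c(B, spec$d)
    f1 <- relu(sweep(flat %*% p$F1, 2, p$bF1, "+"))
    f2 <- relu(sweep(f1 %*% p$F2, 2, p$bF2, "+"))
    relu(sweep(f2 %*% p$F3, 2, p$bF3, "+"))
  }
}

# reconstruction loss on a window tensor, no gradients
ae_eval_loss <- function(spec, p, X, geoms = NULL, chunk = 512L) {
  B <- dim(X)[1]
  tot <- 0
  for (start in seq(1L, B, by = chunk)) {
    rows <- start:min(start + chunk - 1L, B)
    Xb <- X[rows, , , drop = FALSE]
    fw <- ae_forward(spec, p, Xb, geoms)
    ref <- if (spec$kind == "fully_connected") {
      Xf <- Xb; dim(Xf) <- c(length(rows), spec$d); Xf
    } else Xb
    tot <- tot + sum((fw$xhat - ref)^2)
  }
  tot / (B * spec$d)
}

## ---- training --------------------------------------------------------------

# stride-`stride` window tensor (count, nw, nc) from a (scaled) series matrix
window_tensor <- function(xm, nw, stride = 1L) {
  n <- nrow(xm)
  starts <- seq(1L, n - nw + 1L, by = stride)
  out <- array(0, c(length(starts), nw, ncol(xm)))
  idx <- outer(seq_len(nw) - 1L, starts, "+")
  for (ch in seq_len(ncol(xm))) {
    out[, , ch] <- t(matrix(xm[, ch][idx], nrow = nw))
  }
  out
}

#' Train a window autoencoder
#'
#' Minimizes the mean squared reconstruction error of multichannel windows
#' with Adam, holding out a random fraction of windows for validation and
#' early stopping. The returned model carries the parameters of the best
#' validation epoch, the per-channel scaler fitted on the training data, and
#' the full loss history. Training is deterministic given `config$seed`.
#'
#' @param x Training series: data frame/matrix, or a list of them (e.g.
#'   per-regime clips without transitions, the "discontinuous training set"
#'   construction).
#' @param spec Architecture from [build_autoencoder()].
#' @param config Hyperparameters from [ae_config()].
#' @return Object of class `lss_autoencoder`: list with `spec`, `params`,
#'   `scaler`, `config`, `history` (tibble: epoch, train_mse, val_mse),
#'   `best_epoch`, `best_val`.
#' @export
train_autoencoder <- function(x, spec, config = ae_config()) {
  stopifnot(inherits(spec, "lss_ae_spec"))
  clips <- if (is.data.frame(x) || !is.list(x)) list(x) else x
  clips <- lapply(clips, as_ts_matrix)
  if (any(vapply(clips, ncol, integer(1)) != spec$nc)) {
    abort(sprintf("training series must have %d channels to match the spec", spec$nc))
  }
  if (any(vapply(clips, nrow, integer(1)) < spec$nw)) {
    abort("every training clip must be at least nw steps long")
  }
  scaler <- fit_scaler(do.call(rbind, clips), config$scaler)
  tensors <- lapply(clips, function(cm) {
    window_tensor(apply_scaler(cm, scaler), spec$nw, config$train_stride)
  })
  nwin <- sum(vapply(tensors, function(t) dim(t)[1], numeric(1)))
  X <- array(0, c(nwin, spec$nw, spec$nc))
  at <- 0L
  for (t in tensors) {
    X[at + seq_len(dim(t)[1]), , ] <- t
    at <- at + dim(t)[1]
  }
  n_val <- max(1L, as.integer(floor(config$val_fraction * nwin)))
  n_train <- nwin - n_val
  if (n_train < 1L) {
    abort(sprintf(
      "too few windows (%d) for a train/validation split; provide a longer series or smaller train_stride",
      nwin
    ))
  }
  geoms <- if (spec$kind == "convolutional") conv_geoms(spec) else NULL

  withr::with_seed(config$seed, {
    params <- ae_init_params(spec)
    perm <- sample.int(nwin)
    val_idx <- perm[seq_len(n_val)]
    train_idx <- perm[(n_val + 1L):nwin]
    Xval <- X[val_idx, , , drop = FALSE]
    Xtr <- X[train_idx, , , drop = FALSE]

    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_val <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    history <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_train)
      ep_loss <- 0
      n_batch <- 0L
      for (start in seq(1L, n_train, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n_train)]
        gb <- ae_grad(spec, params, Xtr[rows, , , drop = FALSE], geoms)
        step <- step + 1L
        corr1 <- 1 - b1^step
        corr2 <- 1 - b2^step
        for (nm in names(params)) {
          g <- gb$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] - config$learning_rate *
            (adam_m[[nm]] / corr1) / (sqrt(adam_v[[nm]] / corr2) + eps)
        }
        ep_loss <- ep_loss + gb$loss
        n_batch <- n_batch + 1L
      }
      val_loss <- ae_eval_loss(spec, params, Xval, geoms)
      history[[epoch]] <- c(epoch = epoch, train_mse = ep_loss / n_batch,
                            val_mse = val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  hist_df <- as_tibble(do.call(rbind, Filter(Negate(is.null), history)))
  structure(
    list(spec = spec, params = best_params, scaler = scaler, config = config,
         history = hist_df, best_epoch = best_epoch, best_val = best_val,
         n_windows = nwin),
    class = "lss_autoencoder"
  )
}

#' @export
print.lss_autoencoder <- function(x, ...) {
  cat(sprintf(
    "<lss_autoencoder> %s (%d ch x %d steps -> latent %d), best val MSE %.4g at epoch %d/%d\n",
    x$spec$kind, x$spec$nc, x$spec$nw, x$spec$latent_dim,
    x$best_val, x$best_epoch, nrow(x$history)
  ))
  invisible(x)
}

#' @describeIn train_autoencoder Loss history, one row per epoch.
#' @param x,... Method arguments.
#' @export
tidy.lss_autoencoder <- function(x, ...) x$history

#' @describeIn train_autoencoder One-row model summary.
#' @export
glance.lss_autoencoder <- function(x, ...) {
  tibble(
    kind = x$spec$kind, nc = x$spec$nc, nw = x$spec$nw,
    latent_dim = x$spec$latent_dim,
    n_params = ae_param_count(x$spec),
    n_windows = x$n_windows,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mse = x$best_val
  )
}

#' @describeIn train_autoencoder Loss-history curve.
#' @param object Fitted autoencoder.
#' @export
autoplot.lss_autoencoder <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                              names_to = "set", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "reconstruction MSE", color = NULL)
}

#' Encode every subsequence of a series (latent all-subsequence set)
#'
#' Applies the model's scaler and encoder to all stride-1 windows of the
#' series, producing one latent row per subsequence position -- the latent
#' all-subsequence set on which the latent-space matrix profile operates.
#'
#' @param model Trained `lss_autoencoder`.
#' @param x Series to encode (same channel count as the model).
#' @param m Optional window-length check; must equal the model's `nw` when
#'   supplied.
#' @return Numeric matrix, `n - nw + 1` rows by `latent_dim` columns, with
#'   attribute `m` (the window length).
#' @export
encode_all <- function(model, x, m = NULL) {
  stopifnot(inherits(model, "lss_autoencoder"))
  spec <- model$spec
  if (!is.null(m) && m != spec$nw) {
    abort(sprintf("m = %d does not match the model's window length nw = %d",
                  m, spec$nw))
  }
  xm <- as_ts_matrix(x)
  if (ncol(xm) != spec$nc) {
    abort(sprintf("series has %d channels but the model expects %d",
                  ncol(xm), spec$nc))
  }
  if (nrow(xm) < spec$nw) abort("series shorter than the model window")
  X <- window_tensor(apply_scaler(xm, model$scaler), spec$nw, 1L)
  count <- dim(X)[1]
  out <- matrix(0, count, spec$latent_dim)
  chunk <- 1024L
  for (start in seq(1L, count, by = chunk)) {
    rows <- start:min(start + chunk - 1L, count)
    out[rows, ] <- ae_encode_batch(spec, model$params, X[rows, , , drop = FALSE])
  }
  attr(out, "m") <- spec$nw
  out
}

#' Reconstruct windows through the autoencoder
#'
#' Mainly a diagnostic: returns the scaled input windows (flattened) and
#' their reconstructions so reconstruction error can be examined per window.
#'
#' @inheritParams encode_all
#' @param stride Window stride.
#' @return List with matrices `input` and `recon` (rows = windows) and the
#'   overall `mse`.
#' @export
reconstruct_windows <- function(model, x, stride = 1L) {
  spec <- model$spec
  xm <- as_ts_matrix(x)
  X <- window_tensor(apply_scaler(xm, model$scaler), spec$nw, stride)
  fw <- ae_forward(spec, model$params, X)
  B <- dim(X)[1]
  Xf <- X; dim(Xf) <- c(B, spec$d)
  xhat <- fw$xhat
  if (spec$kind == "convolutional") dim(xhat) <- c(B, spec$d)
  list(input = Xf, recon = xhat, mse = mean((xhat - Xf)^2))
}
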