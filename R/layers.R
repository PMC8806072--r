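# Neural-network primitives on base BLAS matrix operations: 1D convolution
# (im2col), batch normalisation, ReLU, dropout, dense, GRU, sigmoid
# self-attention and global average pooling, each with a hand-derived
# backward pass. Activations for per-position data are rank-3 arrays of
# dimension (batch, positions, features); flattening (B, L, F) column-major
# to a (B*L) x F matrix keeps the (b, t) row pairing consistent everywhere.

rep_row <- function(b, n) matrix(b, n, length(b), byrow = TRUE)

flat3 <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3])
  X
}

unflat3 <- function(Xm, B, L) {
  dim(Xm) <- c(B, L, ncol(Xm))
  Xm
}

glorot_init <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_dense <- function(f_in, f_out) {
  list(type = "dense", W = glorot_init(f_in, f_out, f_in, f_out),
       b = numeric(f_out))
}

init_conv <- function(k, f_in, f_out) {
  list(type = "conv", k = k,
       W = glorot_init(k * f_in, f_out, k * f_in, f_out),
       b = numeric(f_out))
}

init_bn <- function(f) {
  list(type = "bn", gamma = rep(1, f), beta = numeric(f),
       run_mean = numeric(f), run_var = rep(1, f),
       momentum = 0.9, eps = 1e-5)
}

init_gru <- function(f_in, h) {
  g <- function() glorot_init(f_in, h, f_in, h)
  u <- function() glorot_init(h, h, h, h)
  list(type = "gru",
       Wz = g(), Uz = u(), bz = numeric(h),
       Wr = g(), Ur = u(), br = numeric(h),
       Wc = g(), Uc = u(), bc = numeric(h))
}

# Trainable tensor names per unit type (BN running stats are state, not
# parameters).
trainable_tensors <- function(type) {
  switch(type,
    dense = c("W", "b"),
    conv = c("W", "b"),
    bn = c("gamma", "beta"),
    gru = c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wc", "Uc", "bc"),
    character(0)
  )
}

## ---- 1D convolution ("same" padding) ----

im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; Fi <- d[3]
  p <- (k - 1L) %/% 2L
  out <- matrix(0, B * L, k * Fi)
  for (j in seq_len(k)) {
    off <- j - 1L - p
    t_dst <- seq.int(max(1L, 1L - off), min(L, L - off))
    S <- array(0, c(B, L, Fi))
    S[, t_dst, ] <- X[, t_dst + off, ]
    dim(S) <- c(B * L, Fi)
    out[, ((j - 1L) * Fi + 1L):(j * Fi)] <- S
  }
  out
}

conv_fw <- function(u, X) {
  d <- dim(X)
  M <- im2col(X, u$k)
  Ym <- M %*% u$W + rep_row(u$b, nrow(M))
  list(Y = unflat3(Ym, d[1], d[2]), cache = list(M = M, dimX = d))
}

conv_bw <- function(u, cache, dY) {
  d <- cache$dimX; B <- d[1]; L <- d[2]; Fi <- d[3]
  dYm <- flat3(dY)
  gW <- crossprod(cache$M, dYm)
  gb <- colSums(dYm)
  dM <- dYm %*% t(u$W)
  p <- (u$k - 1L) %/% 2L
  dX <- array(0, d)
  for (j in seq_len(u$k)) {
    off <- j - 1L - p
    t_dst <- seq.int(max(1L, 1L - off), min(L, L - off))
    dS <- dM[, ((j - 1L) * Fi + 1L):(j * Fi), drop = FALSE]
    dim(dS) <- c(B, L, Fi)
    dX[, t_dst + off, ] <- dX[, t_dst + off, ] + dS[, t_dst, ]
  }
  list(dX = dX, g = list(W = gW, b = gb))
}

## ---- dense ----

dense_fw <- function(u, Xm) {
  list(Y = Xm %*% u$W + rep_row(u$b, nrow(Xm)), cache = list(X = Xm))
}

dense_bw <- function(u, cache, dY) {
  list(dX = dY %*% t(u$W),
       g = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

## ---- batch normalisation (per feature over rows) ----

bn_fw <- function(u, Xm, training) {
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2, mu)
    v <- colMeans(xc^2)
    ivstd <- 1 / sqrt(v + u$eps)
    xhat <- sweep(xc, 2, ivstd, `*`)
    u$run_mean <- u$momentum * u$run_mean + (1 - u$momentum) * mu
    u$run_var <- u$momentum * u$run_var + (1 - u$momentum) * v
    Y <- sweep(xhat, 2, u$gamma, `*`)
    Y <- sweep(Y, 2, u$beta, `+`)
    list(Y = Y, cache = list(xhat = xhat, ivstd = ivstd), unit = u)
  } else {
    xhat <- sweep(sweep(Xm, 2, u$run_mean), 2,
                  1 / sqrt(u$run_var + u$eps), `*`)
    Y <- sweep(sweep(xhat, 2, u$gamma, `*`), 2, u$beta, `+`)
    list(Y = Y, cache = NULL, unit = u)
  }
}

bn_bw <- function(u, cache, dY) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, u$gamma, `*`)
  # standard batch-norm backward in its compact form
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * xhat)
  dX <- sweep(
    dxhat - rep_row(sum_dxhat / n, n) - xhat * rep_row(sum_dxhat_xhat / n, n),
    2, cache$ivstd, `*`
  )
  list(dX = dX, g = list(gamma = colSums(dY * xhat), beta = colSums(dY)))
}

## ---- ReLU / dropout ----

relu_fw <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, cache = mask)
}

relu_bw <- function(cache, dY) {
  dY[!cache] <- 0
  dY
}

dropout_fw <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- array(stats::rbinom(length(X), 1L, 1 - rate), dim(X)) / (1 - rate)
  list(Y = X * mask, cache = mask)
}

dropout_bw <- function(cache, dY) {
  if (is.null(cache)) dY else dY * cache
}

## ---- GRU ----

# `tseq` is the order positions are consumed (1:L forward, L:1 backward
# direction); Y[, t, ] is the hidden state emitted at position t.
gru_fw <- function(u, X, tseq) {
  d <- dim(X); B <- d[1]; L <- d[2]
  H <- ncol(u$Uz)
  h <- matrix(0, B, H)
  Y <- array(0, c(B, L, H))
  Z <- array(0, c(B, L, H)); R <- array(0, c(B, L, H))
  C <- array(0, c(B, L, H)); Hp <- array(0, c(B, L, H))
  for (t in tseq) {
    x <- matrix(X[, t, ], B)
    z <- sigmoid_(x %*% u$Wz + h %*% u$Uz + rep_row(u$bz, B))
    r <- sigmoid_(x %*% u$Wr + h %*% u$Ur + rep_row(u$br, B))
    cc <- tanh(x %*% u$Wc + (r * h) %*% u$Uc + rep_row(u$bc, B))
    Hp[, t, ] <- h
    h <- (1 - z) * h + z * cc
    Z[, t, ] <- z; R[, t, ] <- r; C[, t, ] <- cc; Y[, t, ] <- h
  }
  list(Y = Y, cache = list(X = X, Z = Z, R = R, C = C, Hp = Hp, tseq = tseq))
}

gru_bw <- function(u, cache, dH) {
  X <- cache$X
  d <- dim(X); B <- d[1]
  Hn <- ncol(u$Uz)
  g <- list(Wz = 0 * u$Wz, Uz = 0 * u$Uz, bz = 0 * u$bz,
            Wr = 0 * u$Wr, Ur = 0 * u$Ur, br = 0 * u$br,
            Wc = 0 * u$Wc, Uc = 0 * u$Uc, bc = 0 * u$bc)
  dX <- array(0, d)
  dh_carry <- matrix(0, B, Hn)
  for (t in rev(cache$tseq)) {
    x <- matrix(X[, t, ], B)
    z <- matrix(cache$Z[, t, ], B); r <- matrix(cache$R[, t, ], B)
    cc <- matrix(cache$C[, t, ], B); hp <- matrix(cache$Hp[, t, ], B)
    dh <- matrix(dH[, t, ], B) + dh_carry
    dcc <- dh * z
    dz <- dh * (cc - hp)
    dhp <- dh * (1 - z)
    dac <- dcc * (1 - cc^2)
    g$Wc <- g$Wc + crossprod(x, dac)
    g$Uc <- g$Uc + crossprod(r * hp, dac)
    g$bc <- g$bc + colSums(dac)
    drh <- dac %*% t(u$Uc)
    dr <- drh * hp
    dhp <- dhp + drh * r
    daz <- dz * z * (1 - z)
    g$Wz <- g$Wz + crossprod(x, daz)
    g$Uz <- g$Uz + crossprod(hp, daz)
    g$bz <- g$bz + colSums(daz)
    dhp <- dhp + daz %*% t(u$Uz)
    dar <- dr * r * (1 - r)
    g$Wr <- g$Wr + crossprod(x, dar)
    g$Ur <- g$Ur + crossprod(hp, dar)
    g$br <- g$br + colSums(dar)
    dhp <- dhp + dar %*% t(u$Ur)
    dX[, t, ] <- daz %*% t(u$Wz) + dar %*% t(u$Wr) + dac %*% t(u$Wc)
    dh_carry <- dhp
  }
  list(dX = dX, g = g)
}

## ---- sigmoid self-attention ----

#' Sigmoid self-attention over a position-by-feature matrix
#'
#' Computes `W = sigmoid(H %*% t(H) / sqrt(d))` and returns `W %*% H`,
#' where `d` is the feature dimension: pairwise position similarities are
#' squashed through a sigmoid (rather than a softmax) and used to reweight
#' the input. The `1/sqrt(d)` scaling keeps the similarity logits in a
#' numerically stable range. Shape is preserved.
#'
#' @param H Numeric matrix, positions x features.
#' @return Matrix of the same shape as `H`.
#' @examples
#' self_attention(matrix(0, 4, 8))  # all zeros: weights 0.5, output 0
#' @export
self_attention <- function(H) {
  if (!is.matrix(H) || nrow(H) == 0) abort("`H` must be a non-empty matrix.")
  if (any(!is.finite(H))) abort("`H` must be finite.")
  W <- sigmoid_(tcrossprod(H) / sqrt(ncol(H)))
  W %*% H
}

attn_fw <- function(X) {
  d <- dim(X); B <- d[1]; L <- d[2]; Fi <- d[3]
  Y <- array(0, d)
  Ws <- vector("list", B)
  for (b in seq_len(B)) {
    H <- matrix(X[b, , ], L)
    W <- sigmoid_(tcrossprod(H) / sqrt(Fi))
    Ws[[b]] <- W
    Y[b, , ] <- W %*% H
  }
  list(Y = Y, cache = list(X = X, Ws = Ws))
}

attn_bw <- function(cache, dY) {
  X <- cache$X
  d <- dim(X); B <- d[1]; L <- d[2]; Fi <- d[3]
  dX <- array(0, d)
  for (b in seq_len(B)) {
    H <- matrix(X[b, , ], L)
    dO <- matrix(dY[b, , ], L)
    W <- cache$Ws[[b]]
    dH <- crossprod(W, dO)
    dW <- tcrossprod(dO, H)
    dS <- dW * W * (1 - W)
    dH <- dH + (dS + t(dS)) %*% H / sqrt(Fi)
    dX[b, , ] <- dH
  }
  dX
}

## ---- global average pooling over positions ----

gap_fw <- function(X) {
  d <- dim(X)
  Xp <- aperm(X, c(2, 1, 3))
  dim(Xp) <- c(d[2], d[1] * d[3])
  Y <- matrix(colMeans(Xp), d[1], d[3])
  list(Y = Y, cache = d)
}

gap_bw <- function(cache, dY) {
  d <- cache
  dX <- array(0, d)
  for (t in seq_len(d[2])) dX[, t, ] <- dY / d[2]
  dX
}

## ---- tiling of global channels along the position axis ----

tile_fw <- function(Xm, L) {
  B <- nrow(Xm); Fi <- ncol(Xm)
  aperm(array(Xm, c(B, Fi, L)), c(1, 3, 2))
}

tile_bw <- function(dY) {
  d <- dim(dY)
  Xp <- aperm(dY, c(2, 1, 3))
  dim(Xp) <- c(d[2], d[1] * d[3])
  matrix(colSums(Xp), d[1], d[3])
}

## ---- feature-axis concatenation of rank-3 arrays ----

cat3 <- function(parts) {
  B <- dim(parts[[1]])[1]; L <- dim(parts[[1]])[2]
  fs <- vapply(parts, function(p) dim(p)[3], numeric(1))
  out <- array(0, c(B, L, sum(fs)))
  at <- 0L
  for (p in parts) {
    f <- dim(p)[3]
    out[, , (at + 1L):(at + f)] <- p
    at <- at + f
  }
  out
}

split3 <- function(dY, fs) {
  out <- vector("list", length(fs))
  at <- 0L
  for (i in seq_along(fs)) {
    out[[i]] <- dY[, , (at + 1L):(at + fs[i]), drop = FALSE]
    at <- at + fs[i]
  }
  out
}
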