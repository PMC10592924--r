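# Low-level neural-network primitives for the attention-gated U-Net.
# Activations are arrays [H, W, C]; convolutions are im2col + BLAS gemm.
# Everything is pure R with hand-derived backward passes; determinism is
# exact for fixed inputs and weights.

.im2colCache <- new.env(parent = emptyenv())

# (H*W) x (9*C) index matrix into a zero-padded (H+2) x (W+2) x C array.
# Column order: channel-major, then dx (0..2), then dy (0..2) — row k of a
# weight matrix addresses (dy, dx, channel) = (k-1) %% 3, ((k-1) %/% 3) %% 3,
# (k-1) %/% 9 + 1.
im2colIdx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  pos0 <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  offs <- integer(9L * C)
  k <- 1L
  for (ch in seq_len(C)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        offs[k] <- (ch - 1L) * Hp * Wp + dx * Hp + dy
        k <- k + 1L
      }
    }
  }
  # stored as an integer vector: vector indexing is much faster than
  # matrix indexing and avoids a double coercion on every gather
  idx <- as.integer(outer(pos0, offs, "+"))
  .im2colCache[[key]] <- idx
  idx
}

padZero <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

# 3x3 same-padding convolution.  W: (9*Cin) x Cout, b: length Cout.
# Returns list(out = [H,W,Cout], P = im2col matrix kept for backward).
conv3Forward <- function(x, W, b, keep = TRUE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  P <- padZero(x)[im2colIdx(d[1], d[2], d[3])]
  dim(P) <- c(hw, 9L * d[3])
  Y <- P %*% W
  Y <- Y + rep(b, each = hw)
  dim(Y) <- c(d[1], d[2], ncol(W))
  list(out = Y, P = if (keep) P else NULL)
}

# Backward for conv3Forward. dY: [H,W,Cout].  Returns dX, dW, db;
# dX is skipped when want_dx is FALSE (first layer).
conv3Backward <- function(dY, P, W, xdim, want_dx = TRUE) {
  d <- dim(dY)
  hw <- d[1] * d[2]
  dYm <- dY
  dim(dYm) <- c(hw, d[3])
  dW <- crossprod(P, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (want_dx) {
    Cin <- xdim[3]; Cout <- d[3]
    Wa <- array(W, c(3, 3, Cin, Cout))
    W2 <- matrix(aperm(Wa[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3)),
                 9L * Cout, Cin)
    P2 <- padZero(dY)[im2colIdx(d[1], d[2], Cout)]
    dim(P2) <- c(hw, 9L * Cout)
    dX <- P2 %*% W2
    dim(dX) <- xdim
  }
  list(dX = dX, dW = dW, db = db)
}

# 1x1 convolution on [H,W,C] (a per-pixel linear map).
conv1Forward <- function(x, W, b) {
  d <- dim(x)
  hw <- d[1] * d[2]
  Xm <- x
  dim(Xm) <- c(hw, d[3])
  Y <- Xm %*% W
  Y <- Y + rep(b, each = hw)
  dim(Y) <- c(d[1], d[2], ncol(W))
  list(out = Y, Xm = Xm)
}

conv1Backward <- function(dY, Xm, W, xdim) {
  d <- dim(dY)
  dYm <- dY
  dim(dYm) <- c(d[1] * d[2], d[3])
  dX <- dYm %*% t(W)
  dim(dX) <- xdim
  list(dX = dX, dW = crossprod(Xm, dYm), db = colSums(dYm))
}

reluForward <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}

# 2x2 max pooling, stride 2.  Records the winner for backward routing.
pool2Forward <- function(x) {
  d <- dim(x)
  s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
  a <- x[s1, s2, , drop = FALSE]; b <- x[s1 + 1L, s2, , drop = FALSE]
  cc <- x[s1, s2 + 1L, , drop = FALSE]; dd <- x[s1 + 1L, s2 + 1L, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- (dd == y) & !m1 & !m2 & !m3
  list(out = y, masks = list(m1, m2, m3, m4), xdim = d)
}

pool2Backward <- function(dY, cache) {
  d <- cache$xdim
  s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
  dX <- array(0, d)
  dX[s1, s2, ] <- dY * cache$masks[[1]]
  dX[s1 + 1L, s2, ] <- dY * cache$masks[[2]]
  dX[s1, s2 + 1L, ] <- dY * cache$masks[[3]]
  dX[s1 + 1L, s2 + 1L, ] <- dY * cache$masks[[4]]
  dX
}

# Nearest-neighbour 2x upsampling.
up2Forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2Backward <- function(dY) {
  d <- dim(dY)
  s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
  dY[s1, s2, , drop = FALSE] + dY[s1 + 1L, s2, , drop = FALSE] +
    dY[s1, s2 + 1L, , drop = FALSE] + dY[s1 + 1L, s2 + 1L, , drop = FALSE]
}

sigmoidStable <- function(z) 1 / (1 + exp(-z))
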