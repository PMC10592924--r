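# Attention-gated U-Net: configuration, parameter initialisation, and the
# forward/backward passes through the full encoder/bottleneck/decoder stack.

#' U-Net architecture configuration
#'
#' The network has `depth` encoder blocks (two 3x3 convolutions + ReLU,
#' then 2x max pooling), a bottleneck, and `depth` decoder blocks (2x
#' nearest-neighbour upsampling + 3x3 convolution, an attention-gated skip
#' concatenation, then two 3x3 convolutions), finished by a 1x1 convolution
#' and a sigmoid.  Channel widths grow by `channel_growth` per level from
#' `base_channels`.
#'
#' The shipped default (`depth = 5`, `input_size = 1024`, base 32) is the
#' full-scale architecture; smaller settings are used for desk-scale
#' training and tests.
#'
#' @param depth number of encoder (and decoder) blocks.
#' @param base_channels channels of the first encoder block.
#' @param channel_growth per-level channel multiplier.
#' @param input_size input side length; must be divisible by `2^depth`.
#' @param use_attention gate the skip connections (default TRUE).
#' @return A list of class `UNetConfig`.
#' @export
unetConfig <- function(depth = 5L, base_channels = 32L, channel_growth = 2L,
                       input_size = 1024L, use_attention = TRUE) {
  depth <- as.integer(depth); input_size <- as.integer(input_size)
  if (depth < 1L || base_channels < 4L)
    stopf("depth must be >= 1 and base_channels >= 4",
          class = "cryopickConfigError")
  if (input_size %% (2L^depth) != 0L)
    stopf("input_size (%d) must be divisible by 2^depth (%d)", input_size,
          2L^depth, class = "cryopickConfigError")
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 channel_growth = channel_growth, input_size = input_size,
                 conv_kernel = 3L, use_attention = isTRUE(use_attention)),
            class = c("UNetConfig", "list"))
}

unetChannels <- function(cfg) {
  as.integer(round(cfg$base_channels * cfg$channel_growth^(seq_len(cfg$depth + 1L) - 1L)))
}

heInit <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build an attention-gated U-Net
#'
#' Allocates and He-initialises all weights.  When `seed` is given, the
#' initialisation is reproducible and the caller's RNG state is left
#' untouched.
#'
#' @param cfg a [unetConfig()].
#' @param seed optional integer seed for weight initialisation.
#' @param head_bias initial bias of the output 1x1 convolution.  The
#'   default 0 starts the sigmoid at 0.5; for sparse-foreground tasks a
#'   negative value (e.g. -2, the prior-probability initialisation) starts
#'   the output near the true foreground prevalence and speeds up
#'   probability calibration in short training runs.
#' @return A list of class `UNetModel` with elements `cfg` and `params`
#'   (named list of weight matrices / bias vectors).
#' @seealso [trainUNet()], [predictMask()]
#' @export
buildUNet <- function(cfg = unetConfig(), seed = NULL, head_bias = 0) {
  build <- function() {
    ch <- unetChannels(cfg)
    D <- cfg$depth
    p <- list()
    cin <- 1L
    for (i in seq_len(D)) {
      p[[sprintf("enc%d_c1_W", i)]] <- heInit(9L * cin, ch[i], 9L * cin)
      p[[sprintf("enc%d_c1_b", i)]] <- numeric(ch[i])
      p[[sprintf("enc%d_c2_W", i)]] <- heInit(9L * ch[i], ch[i], 9L * ch[i])
      p[[sprintf("enc%d_c2_b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    p[["bott_c1_W"]] <- heInit(9L * ch[D], ch[D + 1L], 9L * ch[D])
    p[["bott_c1_b"]] <- numeric(ch[D + 1L])
    p[["bott_c2_W"]] <- heInit(9L * ch[D + 1L], ch[D + 1L], 9L * ch[D + 1L])
    p[["bott_c2_b"]] <- numeric(ch[D + 1L])
    for (i in rev(seq_len(D))) {
      cprev <- if (i == D) ch[D + 1L] else ch[i + 1L]
      p[[sprintf("dec%d_up_W", i)]] <- heInit(9L * cprev, ch[i], 9L * cprev)
      p[[sprintf("dec%d_up_b", i)]] <- numeric(ch[i])
      if (cfg$use_attention) {
        ca <- max(ch[i] %/% 2L, 4L)
        p[[sprintf("dec%d_attx_W", i)]] <- heInit(ch[i], ca, ch[i])
        p[[sprintf("dec%d_attx_b", i)]] <- numeric(ca)
        p[[sprintf("dec%d_attg_W", i)]] <- heInit(ch[i], ca, ch[i])
        p[[sprintf("dec%d_attg_b", i)]] <- numeric(ca)
        p[[sprintf("dec%d_attp_W", i)]] <- heInit(ca, 1L, ca)
        p[[sprintf("dec%d_attp_b", i)]] <- numeric(1L)
      }
      p[[sprintf("dec%d_c1_W", i)]] <- heInit(9L * 2L * ch[i], ch[i],
                                              9L * 2L * ch[i])
      p[[sprintf("dec%d_c1_b", i)]] <- numeric(ch[i])
      p[[sprintf("dec%d_c2_W", i)]] <- heInit(9L * ch[i], ch[i], 9L * ch[i])
      p[[sprintf("dec%d_c2_b", i)]] <- numeric(ch[i])
    }
    p[["head_W"]] <- heInit(ch[1L], 1L, ch[1L])
    p[["head_b"]] <- head_bias

    structure(list(cfg = cfg, params = p), class = "UNetModel")
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' @export
print.UNetModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "Attention-gated U-Net: depth %d, base %d channels, input %dx%d, %s; %s parameters\n",
    x$cfg$depth, x$cfg$base_channels, x$cfg$input_size, x$cfg$input_size,
    if (x$cfg$use_attention) "attention gates on" else "no attention gates",
    format(np, big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a U-Net
#' @param model a `UNetModel`.
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# Full forward pass.  `train = TRUE` retains every intermediate needed by
# unetBackward; `force_attention_one` replaces the learned gate by the
# constant 1 (used to verify gate semantics against a plain U-Net).
unetForward <- function(model, x, train = FALSE, force_attention_one = FALSE) {
  cfg <- model$cfg; p <- model$params; D <- cfg$depth
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    stopf("input is %d x %d but the model expects %d x %d", dim(x)[1],
          dim(x)[2], cfg$input_size, cfg$input_size,
          class = "cryopickConfigError")
  K <- list()  # caches
  cur <- x
  for (i in seq_len(D)) {
    c1 <- conv3Forward(cur, p[[sprintf("enc%d_c1_W", i)]],
                       p[[sprintf("enc%d_c1_b", i)]], keep = train)
    r1 <- reluForward(c1$out)
    c2 <- conv3Forward(r1$out, p[[sprintf("enc%d_c2_W", i)]],
                       p[[sprintf("enc%d_c2_b", i)]], keep = train)
    r2 <- reluForward(c2$out)
    pl <- pool2Forward(r2$out)
    if (train)
      K[[sprintf("enc%d", i)]] <- list(xdim = dim(cur), c1 = c1, m1 = r1$mask,
                                       r1dim = dim(r1$out), c2 = c2,
                                       m2 = r2$mask, pool = pl)
    K[[sprintf("skip%d", i)]] <- r2$out
    cur <- pl$out
  }
  b1 <- conv3Forward(cur, p$bott_c1_W, p$bott_c1_b, keep = train)
  rb1 <- reluForward(b1$out)
  b2 <- conv3Forward(rb1$out, p$bott_c2_W, p$bott_c2_b, keep = train)
  rb2 <- reluForward(b2$out)
  if (train)
    K$bott <- list(xdim = dim(cur), c1 = b1, m1 = rb1$mask,
                   r1dim = dim(rb1$out), c2 = b2, m2 = rb2$mask)
  cur <- rb2$out
  for (i in rev(seq_len(D))) {
    up <- up2Forward(cur)
    updim_in <- dim(cur)
    uc <- conv3Forward(up, p[[sprintf("dec%d_up_W", i)]],
                       p[[sprintf("dec%d_up_b", i)]], keep = train)
    ru <- reluForward(uc$out)
    g <- ru$out
    skip <- K[[sprintf("skip%d", i)]]
    if (cfg$use_attention && !force_attention_one) {
      tx <- conv1Forward(skip, p[[sprintf("dec%d_attx_W", i)]],
                         p[[sprintf("dec%d_attx_b", i)]])
      tg <- conv1Forward(g, p[[sprintf("dec%d_attg_W", i)]],
                         p[[sprintf("dec%d_attg_b", i)]])
      rs <- reluForward(tx$out + tg$out)
      ps <- conv1Forward(rs$out, p[[sprintf("dec%d_attp_W", i)]],
                         p[[sprintf("dec%d_attp_b", i)]])
      psi <- sigmoidStable(ps$out)  # [H, W, 1]
      gated <- skip * as.vector(psi)
    } else {
      tx <- tg <- rs <- ps <- psi <- NULL
      gated <- skip
    }
    cat_ <- array(c(gated, g), c(dim(skip)[1:2], dim(skip)[3] + dim(g)[3]))
    c1 <- conv3Forward(cat_, p[[sprintf("dec%d_c1_W", i)]],
                       p[[sprintf("dec%d_c1_b", i)]], keep = train)
    r1 <- reluForward(c1$out)
    c2 <- conv3Forward(r1$out, p[[sprintf("dec%d_c2_W", i)]],
                       p[[sprintf("dec%d_c2_b", i)]], keep = train)
    r2 <- reluForward(c2$out)
    if (train)
      K[[sprintf("dec%d", i)]] <- list(updim_in = updim_in, updim = dim(up),
                                       uc = uc, mu = ru$mask, g = g,
                                       skip = skip, tx = tx, tg = tg,
                                       mrs = if (!is.null(rs)) rs$mask,
                                       rsout = if (!is.null(rs)) rs$out,
                                       ps = ps, psi = psi, cat = cat_,
                                       c1 = c1, m1 = r1$mask,
                                       r1dim = dim(r1$out),
                                       c2 = c2, m2 = r2$mask)
    cur <- r2$out
  }
  hd <- conv1Forward(cur, p$head_W, p$head_b)
  if (train) K$head <- list(Xm = hd$Xm, xdim = dim(cur))
  logits <- hd$out[, , 1L]
  list(prob = sigmoidStable(logits), logits = logits,
       cache = if (train) K else NULL)
}

# Backward pass: dLogits is [S, S] gradient of the loss w.r.t. the logits.
# Returns a named list of gradients matching model$params.
unetBackward <- function(model, cache, dLogits) {
  cfg <- model$cfg; p <- model$params; D <- cfg$depth
  gr <- list()
  hb <- conv1Backward(array(dLogits, c(dim(dLogits), 1L)), cache$head$Xm,
                      p$head_W, cache$head$xdim)
  gr$head_W <- hb$dW; gr$head_b <- hb$db
  dcur <- hb$dX
  for (i in seq_len(D)) {
    Kd <- cache[[sprintf("dec%d", i)]]
    d2 <- dcur * Kd$m2
    b2 <- conv3Backward(d2, Kd$c2$P, p[[sprintf("dec%d_c2_W", i)]], Kd$r1dim)
    gr[[sprintf("dec%d_c2_W", i)]] <- b2$dW
    gr[[sprintf("dec%d_c2_b", i)]] <- b2$db
    d1 <- b2$dX * Kd$m1
    b1 <- conv3Backward(d1, Kd$c1$P, p[[sprintf("dec%d_c1_W", i)]],
                        dim(Kd$cat))
    gr[[sprintf("dec%d_c1_W", i)]] <- b1$dW
    gr[[sprintf("dec%d_c1_b", i)]] <- b1$db
    cs <- dim(Kd$skip)[3]
    dgated <- b1$dX[, , seq_len(cs), drop = FALSE]
    dg <- b1$dX[, , cs + seq_len(dim(Kd$g)[3]), drop = FALSE]
    if (cfg$use_attention) {
      psiv <- as.vector(Kd$psi)
      dskip <- dgated * psiv
      dpsi <- array(rowSums(matrix(dgated * Kd$skip,
                                   prod(dim(Kd$skip)[1:2]), cs)),
                    dim(Kd$psi))
      dps <- dpsi * Kd$psi * (1 - Kd$psi)
      bp <- conv1Backward(dps, Kd$ps$Xm, p[[sprintf("dec%d_attp_W", i)]],
                          dim(Kd$rsout))
      gr[[sprintf("dec%d_attp_W", i)]] <- bp$dW
      gr[[sprintf("dec%d_attp_b", i)]] <- bp$db
      drs <- bp$dX * Kd$mrs
      bx <- conv1Backward(drs, Kd$tx$Xm, p[[sprintf("dec%d_attx_W", i)]],
                          dim(Kd$skip))
      gr[[sprintf("dec%d_attx_W", i)]] <- bx$dW
      gr[[sprintf("dec%d_attx_b", i)]] <- bx$db
      bg <- conv1Backward(drs, Kd$tg$Xm, p[[sprintf("dec%d_attg_W", i)]],
                          dim(Kd$g))
      gr[[sprintf("dec%d_attg_W", i)]] <- bg$dW
      gr[[sprintf("dec%d_attg_b", i)]] <- bg$db
      dskip <- dskip + bx$dX
      dg <- dg + bg$dX
    } else {
      dskip <- dgated
    }
    du <- dg * Kd$mu
    bu <- conv3Backward(du, Kd$uc$P, p[[sprintf("dec%d_up_W", i)]], Kd$updim)
    gr[[sprintf("dec%d_up_W", i)]] <- bu$dW
    gr[[sprintf("dec%d_up_b", i)]] <- bu$db
    dcur <- up2Backward(bu$dX)
    # stash the skip gradient for the encoder sweep
    cache[[sprintf("dskip%d", i)]] <- dskip
  }
  Kb <- cache$bott
  d2 <- dcur * Kb$m2
  b2 <- conv3Backward(d2, Kb$c2$P, p$bott_c2_W, Kb$r1dim)
  gr$bott_c2_W <- b2$dW; gr$bott_c2_b <- b2$db
  d1 <- b2$dX * Kb$m1
  b1 <- conv3Backward(d1, Kb$c1$P, p$bott_c1_W, Kb$xdim)
  gr$bott_c1_W <- b1$dW; gr$bott_c1_b <- b1$db
  dcur <- b1$dX
  for (i in rev(seq_len(D))) {
    Ke <- cache[[sprintf("enc%d", i)]]
    dpost <- pool2Backward(dcur, Ke$pool) + cache[[sprintf("dskip%d", i)]]
    d2 <- dpost * Ke$m2
    b2 <- conv3Backward(d2, Ke$c2$P, p[[sprintf("enc%d_c2_W", i)]], Ke$r1dim)
    gr[[sprintf("enc%d_c2_W", i)]] <- b2$dW
    gr[[sprintf("enc%d_c2_b", i)]] <- b2$db
    d1 <- b2$dX * Ke$m1
    b1 <- conv3Backward(d1, Ke$c1$P, p[[sprintf("enc%d_c1_W", i)]], Ke$xdim,
                        want_dx = i > 1L)  # input gradient unused at layer 1
    gr[[sprintf("enc%d_c1_W", i)]] <- b1$dW
    gr[[sprintf("enc%d_c1_b", i)]] <- b1$db
    dcur <- b1$dX
  }
  gr
}
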