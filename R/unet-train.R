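# Loss functions, the Adam optimiser, the training loop, and inference.

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: batch size 6, learning
#' rate 1e-4, 200 epochs, and a unit-weighted combination of binary
#' cross-entropy and Dice loss.
#'
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of passes over the data (>= 1).
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param bce_weight,dice_weight loss-term weights.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(batch_size = 6L, learning_rate = 1e-4,
                        epochs = 200L, seed = 1L, bce_weight = 1.0,
                        dice_weight = 1.0) {
  if (batch_size < 1L || epochs < 1L || learning_rate <= 0)
    stopf("batch_size >= 1, epochs >= 1 and learning_rate > 0 required",
          class = "cryopickConfigError")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), bce_weight = bce_weight,
                 dice_weight = dice_weight),
            class = c("TrainConfig", "list"))
}

#' Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`
#' with `eps = 1e-6`: 0 for a perfect binary match, approaching 1 for zero
#' overlap.
#'
#' @param pred predicted mask, values in \eqn{[0,1]}.
#' @param target binary reference mask, same shape.
#' @return scalar loss in \eqn{[0, 1]}.
#' @export
diceLoss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stopf("pred and target shapes differ", class = "cryopickShapeError")
  eps <- 1e-6
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Combined segmentation loss
#'
#' `bce_weight * BCE + dice_weight * diceLoss`, where BCE is the mean
#' pixelwise binary cross-entropy (predictions clamped to
#' \eqn{[10^{-7}, 1 - 10^{-7}]}).
#'
#' @inheritParams diceLoss
#' @param bce_weight,dice_weight term weights (default 1 each).
#' @return scalar loss (>= 0).
#' @export
combinedLoss <- function(pred, target, bce_weight = 1.0, dice_weight = 1.0) {
  if (!identical(dim(pred), dim(target)))
    stopf("pred and target shapes differ", class = "cryopickShapeError")
  p <- clamp(pred, 1e-7, 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  bce_weight * bce + dice_weight * diceLoss(pred, target)
}

# Loss and d(loss)/d(logits) in one pass (numerically stable BCE on logits).
lossAndGrad <- function(logits, target, bce_w, dice_w) {
  n <- length(logits)
  p <- sigmoidStable(logits)
  bce <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  eps <- 1e-6
  S1 <- sum(p * target); S2 <- sum(p) + sum(target)
  dice <- 1 - (2 * S1 + eps) / (S2 + eps)
  dldp <- -(2 * target * (S2 + eps) - (2 * S1 + eps)) / (S2 + eps)^2
  dz <- bce_w * (p - target) / n + dice_w * dldp * p * (1 - p)
  list(loss = bce_w * bce + dice_w * dice, dz = dz)
}

#' Train a U-Net on image/mask pairs
#'
#' Minibatch Adam with seeded shuffling.  Images are the denoised 8-bit
#' micrographs (0-255; internally scaled to \eqn{[0,1]}); masks are binary.
#' With a fixed `tcfg$seed` and fixed initial weights the run is exactly
#' reproducible.
#'
#' @param model a `UNetModel` from [buildUNet()].
#' @param images list of numeric matrices, each `input_size x input_size`.
#' @param masks list of binary matrices matching `images`.
#' @param tcfg a [trainConfig()].
#' @param validation optional `list(images =, masks =)` scored (loss only)
#'   after every epoch.
#' @param verbose print a line per epoch.
#' @return `list(model, history)` where `history` is a data.frame with
#'   per-epoch mean training loss (and validation loss when given).
#' @export
trainUNet <- function(model, images, masks, tcfg = trainConfig(),
                      validation = NULL, verbose = FALSE) {
  if (length(images) == 0L)
    stopf("empty training set", class = "cryopickConfigError")
  if (length(images) != length(masks))
    stopf("images and masks differ in length", class = "cryopickConfigError")
  S <- model$cfg$input_size
  for (k in seq_along(images))
    if (!all(dim(images[[k]]) == S) || !all(dim(masks[[k]]) == S))
      stopf("image/mask %d is not %d x %d", k, S, S,
            class = "cryopickShapeError")
  p <- model$params
  mAdam <- lapply(p, function(w) w * 0)
  vAdam <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  t <- 0L
  hist_train <- numeric(tcfg$epochs)
  hist_val <- if (is.null(validation)) NULL else numeric(tcfg$epochs)
  scale01 <- function(img) if (max(img) > 1.5) img / 255 else img
  withSeed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(length(images))
      losses <- numeric(0)
      bstart <- seq(1L, length(ord), by = tcfg$batch_size)
      for (bs in bstart) {
        batch <- ord[bs:min(bs + tcfg$batch_size - 1L, length(ord))]
        gacc <- NULL
        bloss <- 0
        for (k in batch) {
          x <- scale01(images[[k]])
          fwd <- unetForward(model, x, train = TRUE)
          lg <- lossAndGrad(fwd$logits, masks[[k]], tcfg$bce_weight,
                            tcfg$dice_weight)
          bloss <- bloss + lg$loss
          gr <- unetBackward(model, fwd$cache, lg$dz)
          gacc <- if (is.null(gacc)) gr else
            mapply(`+`, gacc, gr[names(gacc)], SIMPLIFY = FALSE)
        }
        nb <- length(batch)
        losses <- c(losses, bloss / nb)
        t <- t + 1L
        for (nm in names(p)) {
          g <- gacc[[nm]] / nb
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
          mh <- mAdam[[nm]] / (1 - b1^t)
          vh <- vAdam[[nm]] / (1 - b2^t)
          p[[nm]] <- p[[nm]] - tcfg$learning_rate * mh / (sqrt(vh) + epsA)
        }
        model$params <- p
      }
      hist_train[ep] <- mean(losses)
      if (!is.null(validation)) {
        vl <- vapply(seq_along(validation$images), function(k) {
          fwd <- unetForward(model, scale01(validation$images[[k]]))
          combinedLoss(fwd$prob, validation$masks[[k]], tcfg$bce_weight,
                       tcfg$dice_weight)
        }, numeric(1))
        hist_val[ep] <- mean(vl)
      }
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.5f%s", ep, tcfg$epochs,
                        hist_train[ep],
                        if (is.null(hist_val)) "" else
                          sprintf(", val %.5f", hist_val[ep])))
    }
  })
  history <- data.frame(epoch = seq_len(tcfg$epochs), train_loss = hist_train)
  if (!is.null(hist_val)) history$val_loss <- hist_val
  list(model = model, history = history)
}

#' Predict a segmentation mask for one image
#'
#' Runs the forward pass in inference mode (deterministic, no caches).
#'
#' @param model a `UNetModel`.
#' @param img numeric matrix, `input_size x input_size`; 8-bit images
#'   (max > 1.5) are scaled to \eqn{[0,1]} automatically.
#' @param micrographId label carried into the output mask.
#' @param force_attention_one internal: bypass the learned attention gates
#'   with the constant 1.
#' @return A [SegmentationMask-class] of per-pixel particle probabilities.
#' @export
predictMask <- function(model, img, micrographId = "micrograph",
                        force_attention_one = FALSE) {
  x <- if (max(img) > 1.5) img / 255 else img
  fwd <- unetForward(model, x, train = FALSE,
                     force_attention_one = force_attention_one)
  SegmentationMask(clamp(fwd$prob, 0, 1), micrographId)
}

#' Save / load a U-Net checkpoint
#'
#' The checkpoint embeds the architecture configuration alongside the
#' weights, so `loadUNet` needs no other information.
#'
#' @param model a `UNetModel`.
#' @param path checkpoint path.
#' @return `saveUNet`: `path` invisibly; `loadUNet`: the `UNetModel`.
#' @export
saveUNet <- function(model, path) {
  saveRDS(list(format = "cryopick-unet-v1", cfg = unclass(model$cfg),
               params = model$params), path)
  invisible(path)
}

#' @rdname saveUNet
#' @export
loadUNet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cryopick-unet-v1"))
    stopf("%s is not a cryopick U-Net checkpoint", path,
          class = "cryopickFormatError")
  structure(list(cfg = do.call(unetConfig, obj$cfg[c("depth", "base_channels",
                                                     "channel_growth",
                                                     "input_size",
                                                     "use_attention")]),
                 params = obj$params), class = "UNetModel")
}
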