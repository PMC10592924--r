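# Shared helpers: small deterministic objects used across test files.

# A micrograph with a single dark disc on Gaussian noise, plus the disc mask.
discOnNoise <- function(size = 96, d = 30, snr = 0.3, seed = 1) {
  withr::local_seed(seed)
  img <- matrix(rnorm(size * size, mean = 0.5, sd = 0.1), size, size)
  cx <- (size - 1) / 2; cy <- cx; r <- d / 2
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), times = size), size)
  disc <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  img[disc] <- img[disc] - snr * 0.1
  list(img = img, disc = disc)
}

# Random proposal table in a model frame of the given size.
randomProposals <- function(n, frame = 1024, seed = 1) {
  withr::local_seed(seed)
  w <- pmax(2, round(rnorm(n, 40, 12)))
  h <- pmax(2, round(rnorm(n, 40, 12)))
  data.frame(
    bbox_x = round(runif(n, 0, frame - w - 1)),
    bbox_y = round(runif(n, 0, frame - h - 1)),
    bbox_w = w, bbox_h = h,
    pred_iou = round(runif(n, 0.85, 1), 3),
    confidence = round(runif(n, 80, 100), 2),
    mask_area = round(w * h * runif(n, 0.5, 0.8)))
}

# Straight-line re-implementation of the size-consensus postprocessing,
# used as an independent oracle: no shared code with the package internals.
oraclePostprocess <- function(props, o_w, o_h, iou_min = 0.94,
                              th_fraction = 0.1, divisor = 3,
                              model_size = 1024) {
  keep <- props[props$pred_iou > iou_min, , drop = FALSE]
  if (nrow(keep) == 0) return(data.frame(new_x = numeric(0),
                                         new_y = numeric(0), d = numeric(0)))
  modeOf <- function(v) {
    r <- round(v); tb <- table(r)
    min(as.numeric(names(tb)[tb == max(tb)]))
  }
  m_w <- modeOf(keep$bbox_w); m_h <- modeOf(keep$bbox_h)
  d <- sqrt((m_w * o_w / model_size)^2 + (m_h * o_h / model_size)^2)
  th <- th_fraction * sqrt(m_w^2 + m_h^2)
  ok <- keep$bbox_w > m_w - th / divisor & keep$bbox_w < m_w + th &
        keep$bbox_h > m_h - th / divisor & keep$bbox_h < m_h + th
  keep <- keep[ok, , drop = FALSE]
  data.frame(new_x = (keep$bbox_x + keep$bbox_w / 2) * o_w / model_size,
             new_y = (keep$bbox_y + keep$bbox_h / 2) * o_h / model_size,
             d = rep(d, nrow(keep)))
}
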