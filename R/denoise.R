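# Six-stage contrast-enhancement / denoising chain applied to every
# micrograph before segmentation:
#   Gaussian -> standard normalization (0-255) -> fast non-local means ->
#   adaptive Wiener -> CLAHE -> guided filter (CLAHE result as guide,
#   Wiener result as source).

#' Denoising chain configuration
#'
#' Parameters of the six-stage denoising chain.  All sizes are in pixels.
#' Window and patch sizes must be odd and at least 3.
#'
#' @param gaussian_sigma standard deviation of the initial Gaussian blur.
#' @param nlm_strength non-local means filter strength `h` (on the 0-255
#'   intensity scale).
#' @param nlm_patch odd patch size for non-local means similarity.
#' @param nlm_search odd search-window size for non-local means.
#' @param wiener_window odd window for the adaptive Wiener filter.
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile count per axis.
#' @param guided_radius guided-filter box radius.
#' @param guided_eps guided-filter regularizer (on the normalized \[0,1\]
#'   intensity scale).
#' @return A list of class `DenoiseConfig`.
#' @export
denoiseConfig <- function(gaussian_sigma = 1.0, nlm_strength = 10,
                          nlm_patch = 7, nlm_search = 21,
                          wiener_window = 5, clahe_clip = 2.0,
                          clahe_tiles = 8, guided_radius = 8,
                          guided_eps = 0.01) {
  cfg <- list(gaussian_sigma = gaussian_sigma, nlm_strength = nlm_strength,
              nlm_patch = as.integer(nlm_patch),
              nlm_search = as.integer(nlm_search),
              wiener_window = as.integer(wiener_window),
              clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
              guided_radius = as.integer(guided_radius),
              guided_eps = guided_eps)
  for (f in c("nlm_patch", "nlm_search", "wiener_window"))
    if (cfg[[f]] < 3L || cfg[[f]] %% 2L == 0L)
      stopf("%s must be odd and >= 3", f, class = "cryopickConfigError")
  if (cfg$clahe_tiles < 1L)
    stopf("clahe_tiles must be >= 1", class = "cryopickConfigError")
  if (cfg$guided_eps <= 0)
    stopf("guided_eps must be > 0", class = "cryopickConfigError")
  structure(cfg, class = c("DenoiseConfig", "list"))
}

#' Standard-normalize an image to the 0-255 grayscale range
#'
#' Subtracts the mean, divides by the standard deviation, clips to
#' \eqn{\pm 3} standard deviations (bounding hot-pixel influence) and maps
#' the result affinely to \eqn{[0, 255]}.  A constant image maps to the
#' mid-gray value 128.
#'
#' @param img numeric matrix.
#' @return numeric matrix, same shape, values in \eqn{[0, 255]}.
#' @export
standardNormalize <- function(img) {
  stopifnot(all(is.finite(img)))
  s <- stats::sd(as.vector(img))
  if (!is.finite(s) || s == 0)
    return(matrix(128, nrow(img), ncol(img)))
  z <- clamp((img - mean(img)) / s, -3, 3)
  (z + 3) / 6 * 255
}

# Fast non-local means on a 0-255 image; integral-image patch distances,
# one pass per search offset.
fastNLMeans <- function(img, h = 10, patch = 7, search = 21) {
  pr <- (patch - 1L) %/% 2L
  sr <- (search - 1L) %/% 2L
  P <- padReflect(img, sr + pr)
  H <- nrow(img); W <- ncol(img)
  # coordinates of the original image inside the padded frame
  o <- sr + pr
  wsum <- matrix(0, H, W)
  vsum <- matrix(0, H, W)
  h2 <- h * h
  np <- patch * patch
  ri <- (o + 1):(o + H); ci <- (o + 1):(o + W)
  for (dy in -sr:sr) {
    for (dx in -sr:sr) {
      Q <- P[(o + 1 + dy - pr):(o + H + dy + pr),
             (o + 1 + dx - pr):(o + W + dx + pr), drop = FALSE]
      R <- P[(o + 1 - pr):(o + H + pr), (o + 1 - pr):(o + W + pr),
             drop = FALSE]
      d2 <- (R - Q)^2
      S <- integralImage(d2)
      # patch sums centred on each original pixel
      D <- (S[(2 * pr + 2):(H + 2 * pr + 1), (2 * pr + 2):(W + 2 * pr + 1)] -
            S[1:H, (2 * pr + 2):(W + 2 * pr + 1)] -
            S[(2 * pr + 2):(H + 2 * pr + 1), 1:W] + S[1:H, 1:W]) / np
      wgt <- exp(-D / h2)
      wsum <- wsum + wgt
      vsum <- vsum + wgt * P[ri + dy, ci + dx]
    }
  }
  vsum / wsum
}

# Adaptive (wiener2-style) local Wiener filter: shrink toward the local mean
# by the locally estimated signal fraction; noise power estimated as the
# mean local variance.
wienerFilter <- function(img, window = 5) {
  r <- (window - 1L) %/% 2L
  m <- boxMean(img, r)
  m2 <- boxMean(img^2, r)
  v <- pmax(m2 - m^2, 0)
  noise <- mean(v)
  gain <- pmax(v - noise, 0) / pmax(v, .Machine$double.eps)
  m + gain * (img - m)
}

# Edge-preserving guided filter (box-filter form): smooth `src` using the
# local linear model of `guide`.  Both on [0, 1].
guidedFilter <- function(src, guide, radius = 8, eps = 0.01) {
  mI <- boxMean(guide, radius)
  mp <- boxMean(src, radius)
  corrI <- boxMean(guide * guide, radius)
  corrIp <- boxMean(guide * src, radius)
  varI <- pmax(corrI - mI^2, 0)
  covIp <- corrIp - mI * mp
  a <- covIp / (varI + eps)
  b <- mp - a * mI
  boxMean(a, radius) * guide + boxMean(b, radius)
}

#' Denoise a micrograph with the six-stage chain
#'
#' Applies, in order: Gaussian smoothing, standard normalization to 0-255,
#' fast non-local means, adaptive Wiener filtering, CLAHE contrast
#' enhancement, and finally a guided filter that takes the CLAHE result as
#' the guide and the Wiener result as the source.  The chain is
#' deterministic: identical input and configuration give bit-identical
#' output.
#'
#' @param m a [Micrograph-class] (or a plain numeric matrix).
#' @param cfg a [denoiseConfig()] list.
#' @return integer matrix (0-255, 8-bit range), same shape as the input.
#' @examples
#' m <- Micrograph(matrix(rnorm(96 * 96), 96, 96), "demo")
#' d <- denoiseMicrograph(m, denoiseConfig(nlm_search = 7))
#' range(d)
#' @export
denoiseMicrograph <- function(m, cfg = denoiseConfig()) {
  img <- if (is(m, "Micrograph")) pixels(m) else m
  stopifnot(is.matrix(img))
  biggest <- max(cfg$nlm_search + cfg$nlm_patch, cfg$wiener_window,
                 2L * cfg$guided_radius + 1L)
  if (min(dim(img)) < biggest)
    stopf("image (%d x %d) smaller than the largest configured window (%d)",
          nrow(img), ncol(img), biggest, class = "cryopickConfigError")
  g <- if (cfg$gaussian_sigma > 0)
    as.matrix(EBImage::gblur(img, sigma = cfg$gaussian_sigma)) else img
  n <- standardNormalize(g)
  nl <- fastNLMeans(n, h = cfg$nlm_strength, patch = cfg$nlm_patch,
                    search = cfg$nlm_search)
  wn <- wienerFilter(nl, window = cfg$wiener_window)
  wn01 <- clamp(wn / 255, 0, 1)
  # equalization of a constant image is the identity (and CLAHE rejects it)
  cl <- if (diff(range(wn01)) == 0) wn01 else
    as.matrix(EBImage::clahe(wn01, nx = cfg$clahe_tiles,
                             ny = cfg$clahe_tiles, limit = cfg$clahe_clip,
                             keep.range = TRUE))
  gf <- guidedFilter(wn01, cl, radius = cfg$guided_radius,
                     eps = cfg$guided_eps)
  out <- round(clamp(gf, 0, 1) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Resize an image to the model frame
#'
#' Bilinear resize to a square `out_size` grid.  Aspect ratio is not
#' preserved: each axis is scaled independently, matching the coordinate
#' rescaling used throughout the pipeline (`o_w/out_size` on x,
#' `o_h/out_size` on y).
#'
#' @param img numeric matrix.
#' @param out_size output side length (default 1024).
#' @return numeric `out_size x out_size` matrix.
#' @export
resizeToModel <- function(img, out_size = 1024L) {
  stopifnot(is.matrix(img), out_size >= 32)
  if (nrow(img) == out_size && ncol(img) == out_size) return(img)
  as.matrix(EBImage::resize(img, w = out_size, h = out_size,
                            antialias = FALSE))
}
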