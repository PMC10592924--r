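# Internal numeric helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run expr with a private RNG stream; restores the caller's .Random.seed.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Summed-area table; S[i+1, j+1] = sum(x[1:i, 1:j]) with a zero first row/col.
integralImage <- function(x) {
  s <- apply(x, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Mean over the (2r+1)^2 window centred at each pixel, window clipped at the
# borders (divides by the number of in-image pixels, so no edge bias).
boxMean <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  S <- integralImage(x)
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  # S is (h+1) x (w+1); block sum over rows r1..r2, cols c1..c2
  A <- S[r2 + 1L, c2 + 1L, drop = FALSE]
  B <- S[r1, c2 + 1L, drop = FALSE]
  C <- S[r2 + 1L, c1, drop = FALSE]
  D <- S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  (A - B - C + D) / cnt
}

# Pad a matrix by `k` pixels on every side, reflecting across the border.
padReflect <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rev(seq_len(min(k, h))), seq_len(h), h + 1L - rev(seq_len(min(k, h))))
  ci <- c(rev(seq_len(min(k, w))), seq_len(w), w + 1L - rev(seq_len(min(k, w))))
  x[ri, ci, drop = FALSE]
}

# 8-connected component labelling: EBImage::bwlabel (4-connected) followed by
# a union-find merge of labels that touch diagonally.
labelComponents8 <- function(mask) {
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), findRoot, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Bounding boxes of labelled components in the package's 0-based XYWH
# convention.  Returns a data.frame with one row per label, plus pixel areas.
componentBoxes <- function(lab) {
  nl <- max(lab)
  if (nl == 0L)
    return(data.frame(label = integer(0), bbox_x = numeric(0),
                      bbox_y = numeric(0), bbox_w = numeric(0),
                      bbox_h = numeric(0), mask_area = integer(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  row <- (idx - 1L) %% nrow(lab) + 1L
  col <- (idx - 1L) %/% nrow(lab) + 1L
  rmin <- tapply(row, l, min); rmax <- tapply(row, l, max)
  cmin <- tapply(col, l, min); cmax <- tapply(col, l, max)
  area <- tabulate(l, nbins = nl)
  data.frame(label = seq_len(nl),
             bbox_x = as.numeric(cmin - 1L),
             bbox_y = as.numeric(rmin - 1L),
             bbox_w = as.numeric(cmax - cmin + 1L),
             bbox_h = as.numeric(rmax - rmin + 1L),
             mask_area = area)
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cryopickError")))
}
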