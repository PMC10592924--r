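# Seeded synthetic micrograph generator.  Emulates the statistical
# structure the pipeline assumes: dark quasi-circular / elliptical /
# rod-shaped particles of a shared size mode on a lighter noisy background,
# plus confounders (large dark ice patches, a dark carbon-edge band) that
# are deliberately absent from the ground truth.

#' Synthetic micrograph specification
#'
#' Defaults describe a desk-scale 256 x 256 micrograph: a dozen dark
#' particles with a tight size distribution (diameter ~ Normal(30, 2) px,
#' truncated to \[6, o_w/4\]), mostly circular with some mild ellipses and
#' short rods, at a foreground-contrast to background-noise ratio of 2,
#' one ice patch, and a carbon edge.
#'
#' @param o_w,o_h output size in pixels.
#' @param n_particles particle count.
#' @param shape_mix proportions of disc/ellipse/rod shapes (length 3,
#'   normalised internally).
#' @param diameter_mean,diameter_sd particle diameter distribution (px).
#' @param snr foreground contrast over background noise sd.
#' @param n_ice_patches number of large dark ice blobs (not ground truth).
#' @param carbon_edge add a dark band along one image edge (not ground
#'   truth).
#' @param min_separation minimum center-to-center particle distance
#'   (default `1.2 * diameter_mean`).
#' @param seed integer seed; the generated triple is fully determined by it.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(o_w = 256L, o_h = 256L, n_particles = 12L,
                          shape_mix = c(disc = 0.7, ellipse = 0.2,
                                        rod = 0.1),
                          diameter_mean = 30, diameter_sd = 2, snr = 2,
                          n_ice_patches = 1L, carbon_edge = TRUE,
                          min_separation = NULL, seed = 1L) {
  if (diameter_mean <= 4)
    stopf("diameter_mean must be > 4", class = "cryopickConfigError")
  if (snr <= 0)
    stopf("snr must be > 0", class = "cryopickConfigError")
  if (is.null(min_separation)) min_separation <- 1.2 * diameter_mean
  structure(list(o_w = as.integer(o_w), o_h = as.integer(o_h),
                 n_particles = as.integer(n_particles),
                 shape_mix = shape_mix / sum(shape_mix),
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 snr = snr, n_ice_patches = as.integer(n_ice_patches),
                 carbon_edge = isTRUE(carbon_edge),
                 min_separation = min_separation, seed = as.integer(seed)),
            class = c("SyntheticSpec", "list"))
}

# Soft-edged elliptical/rod stamp on [0, 1]: 1 deep inside, 0 outside,
# ~1.5 px smooth transition so measured interior contrast matches `depth`.
.stampShape <- function(h, w, cx, cy, rx, ry, theta, rod = FALSE) {
  j0 <- max(1L, floor(cx - rx - ry - 2)); j1 <- min(w, ceiling(cx + rx + ry + 2) + 1)
  i0 <- max(1L, floor(cy - rx - ry - 2)); i1 <- min(h, ceiling(cy + rx + ry + 2) + 1)
  jj <- j0:j1; ii <- i0:i1
  X <- matrix(rep(jj - 1, each = length(ii)) - cx, length(ii))
  Y <- matrix(rep(ii - 1, times = length(jj)) - cy, length(ii))
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  if (rod) {
    # capsule: segment of half-length rx - ry with cap radius ry
    hu <- pmax(abs(u) - (rx - ry), 0)
    distv <- sqrt(hu^2 + v^2) / ry
  } else {
    distv <- sqrt((u / rx)^2 + (v / ry)^2)
  }
  s <- clamp((1 - distv) / (1.5 / min(rx, ry)) , 0, 1)
  list(i = ii, j = jj, s = s)
}

#' Generate one synthetic labelled micrograph
#'
#' Places `n_particles` dark shapes with rejection-sampled centers (full
#' shape inside the frame, pairwise separation at least `min_separation`,
#' clear of the carbon band), adds confounders, then additive Gaussian
#' noise.  The image, the exact coordinate table and the rendered binary
#' ground-truth mask are returned; confounders never enter the ground
#' truth, so picking one is a false positive by construction.
#'
#' @param spec a [syntheticSpec()].
#' @return `list(micrograph, particles, mask, confounders)`:
#'   a [Micrograph-class], a [ParticleSet-class], a binary
#'   [SegmentationMask-class] at the micrograph's own resolution, and a
#'   binary matrix marking ice/carbon confounder pixels.
#' @examples
#' g <- generateMicrograph(syntheticSpec(n_particles = 5, seed = 7))
#' nParticles(g$particles)
#' @export
generateMicrograph <- function(spec = syntheticSpec()) {
  withSeed(spec$seed, {
    w <- spec$o_w; h <- spec$o_h
    noise_sd <- 0.1
    contrast <- spec$snr * noise_sd
    bg <- 0.6
    img <- matrix(bg, h, w)
    conf <- matrix(0, h, w)
    carbon_w <- 0L
    carbon_side <- NA_character_
    if (spec$carbon_edge) {
      carbon_w <- as.integer(round(stats::runif(1, 0.06, 0.12) * w))
      carbon_side <- sample(c("left", "right", "top", "bottom"), 1)
      band <- switch(carbon_side,
        left = cbind(row = rep(seq_len(h), carbon_w),
                     col = rep(seq_len(carbon_w), each = h)),
        right = cbind(row = rep(seq_len(h), carbon_w),
                      col = rep(w - seq_len(carbon_w) + 1L, each = h)),
        top = cbind(row = rep(seq_len(carbon_w), each = w),
                    col = rep(seq_len(w), carbon_w)),
        bottom = cbind(row = rep(h - seq_len(carbon_w) + 1L, each = w),
                       col = rep(seq_len(w), carbon_w)))
      img[band] <- img[band] - 0.8 * contrast
      conf[band] <- 1
    }
    # truncated-normal diameters
    dmax <- w / 4
    diam <- numeric(spec$n_particles)
    for (k in seq_len(spec$n_particles)) {
      repeat {
        d <- stats::rnorm(1, spec$diameter_mean, spec$diameter_sd)
        if (d >= 6 && d <= dmax) break
      }
      diam[k] <- d
    }
    # rejection-sample centers
    xs <- ys <- numeric(0)
    budget <- 200L * max(spec$n_particles, 1L)
    margin_x <- function(d) d / 2 + 2
    for (k in seq_len(spec$n_particles)) {
      placed <- FALSE
      mg <- margin_x(diam[k])
      while (budget > 0L) {
        budget <- budget - 1L
        cx <- stats::runif(1, mg, w - 1 - mg)
        cy <- stats::runif(1, mg, h - 1 - mg)
        if (spec$carbon_edge) {
          clear <- switch(carbon_side,
            left = cx - diam[k] / 2 > carbon_w,
            right = cx + diam[k] / 2 < w - carbon_w,
            top = cy - diam[k] / 2 > carbon_w,
            bottom = cy + diam[k] / 2 < h - carbon_w)
          if (!clear) next
        }
        if (length(xs) == 0 ||
            all(sqrt((xs - cx)^2 + (ys - cy)^2) >= spec$min_separation)) {
          xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break
        }
      }
      if (!placed)
        stopf("could not place %d particles at min_separation %.1f in %d x %d",
              spec$n_particles, spec$min_separation, w, h,
              class = "cryopickPackingError")
    }
    # draw particles
    shapes <- if (spec$n_particles > 0)
      sample(c("disc", "ellipse", "rod"), spec$n_particles, replace = TRUE,
             prob = spec$shape_mix) else character(0)
    for (k in seq_len(spec$n_particles)) {
      r <- diam[k] / 2
      st <- switch(shapes[k],
        disc = .stampShape(h, w, xs[k], ys[k], r, r, 0),
        ellipse = .stampShape(h, w, xs[k], ys[k], r, r / 1.3,
                              stats::runif(1, 0, pi)),
        rod = .stampShape(h, w, xs[k], ys[k], r, r / 1.8,
                          stats::runif(1, 0, pi), rod = TRUE))
      img[st$i, st$j] <- img[st$i, st$j] - contrast * st$s
    }
    # ice patches: large, soft, dark blobs
    for (k in seq_len(spec$n_ice_patches)) {
      rad <- stats::runif(1, 0.10, 0.18) * w
      cx <- stats::runif(1, rad / 2, w - 1 - rad / 2)
      cy <- stats::runif(1, rad / 2, h - 1 - rad / 2)
      st <- .stampShape(h, w, cx, cy, rad, rad * stats::runif(1, 0.7, 1),
                        stats::runif(1, 0, pi))
      img[st$i, st$j] <- img[st$i, st$j] - 0.6 * contrast * st$s
      cf <- conf[st$i, st$j]; cf[st$s > 0.5] <- 1; conf[st$i, st$j] <- cf
    }
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    id <- sprintf("synth_seed%d", spec$seed)
    ps <- ParticleSet(id, new_x = xs, new_y = ys, d = diam)
    mask <- renderMask(ps, o_w = w, o_h = h, out_size = max(w, h))
    mask@micrographId <- id
    list(micrograph = Micrograph(img, id), particles = ps, mask = mask,
         confounders = conf)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` triples (MRC micrograph, coordinate CSV, PNG mask)
#' with per-image seeds derived from the master seed, plus a JSON manifest
#' listing every path and seed.
#'
#' @param spec a [syntheticSpec()]; its `seed` is the master seed.
#' @param n_images number of micrographs.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
generateDataset <- function(spec, n_images, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- spec
    si$seed <- as.integer((spec$seed + i * 9973L) %% .Machine$integer.max)
    g <- generateMicrograph(si)
    stem <- sprintf("synth_%03d", i)
    mrc <- file.path(out_dir, paste0(stem, ".mrc"))
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    png <- file.path(out_dir, paste0(stem, "_mask.png"))
    writeMRC(g$micrograph, mrc)
    writeParticleCSV(g$particles, csv)
    EBImage::writeImage(maskValues(g$mask), png)
    entries[[i]] <- list(stem = stem, seed = si$seed, mrc = mrc, csv = csv,
                         mask = png, n_particles = nParticles(g$particles))
  }
  manifest <- list(master_seed = spec$seed, n_images = n_images,
                   images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
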