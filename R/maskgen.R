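# Mask-proposal stage: turn a segmentation probability map into scored
# per-particle proposals, apply confidence filtering and greedy NMS.
# Proposals are data.frames with columns bbox_x, bbox_y, bbox_w, bbox_h
# (0-based XYWH in model-frame pixels), pred_iou in [0,1], confidence on a
# 0-100 scale, and mask_area (foreground pixel count).

#' Mask-proposal configuration
#'
#' @param nms_iou IoU threshold of the greedy non-maximum suppression
#'   (default 0.7).
#' @param min_confidence proposals with confidence at or below this 0-100
#'   value are dropped (default 88.0).
#' @param binarize_threshold probability threshold that defines proposal
#'   components (default 0.5).
#' @param min_area components smaller than this (pixels) are removed as
#'   artifacts (default 16).
#' @param fill_holes fill interior holes of components (default TRUE).
#' @param grid_points_per_side proposal grid density for an external
#'   promptable-backend adapter; unused by the built-in proposer.
#' @return A list of class `MaskGenConfig`.
#' @export
maskGenConfig <- function(nms_iou = 0.7, min_confidence = 88.0,
                          binarize_threshold = 0.5, min_area = 16L,
                          fill_holes = TRUE, grid_points_per_side = 32L) {
  if (nms_iou <= 0 || nms_iou >= 1)
    stopf("nms_iou must be in (0, 1)", class = "cryopickConfigError")
  if (min_area < 0)
    stopf("min_area must be >= 0", class = "cryopickConfigError")
  structure(list(nms_iou = nms_iou, min_confidence = min_confidence,
                 binarize_threshold = binarize_threshold,
                 min_area = as.integer(min_area),
                 fill_holes = isTRUE(fill_holes),
                 grid_points_per_side = as.integer(grid_points_per_side)),
            class = c("MaskGenConfig", "list"))
}

#' Intersection-over-union of two XYWH boxes
#'
#' @param a,b numeric vectors `c(x, y, w, h)` (0-based top-left origin).
#' @return IoU in \eqn{[0, 1]}; 0 for disjoint boxes.
#' @export
boxIoU <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stopf("zero-area bounding box", class = "cryopickValidationError")
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Greedy non-maximum suppression over proposals
#'
#' Proposals are visited in descending `pred_iou` order (ties broken by
#' descending confidence, then ascending `bbox_x`, then `bbox_y`); each kept
#' proposal suppresses all later ones whose box IoU with it exceeds
#' `nms_iou`.
#'
#' @param proposals proposal data.frame (see [proposeMasks()]).
#' @param nms_iou suppression threshold.
#' @return The surviving subset of `proposals`, original order of the
#'   survivors preserved by score rank.
#' @export
nmsProposals <- function(proposals, nms_iou = 0.7) {
  n <- nrow(proposals)
  if (n <= 1L) return(proposals)
  ord <- order(-proposals$pred_iou, -proposals$confidence,
               proposals$bbox_x, proposals$bbox_y)
  keep <- logical(n)
  boxes <- as.matrix(proposals[, c("bbox_x", "bbox_y", "bbox_w", "bbox_h")])
  alive <- rep(TRUE, n)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (!alive[i]) next
    keep[i] <- TRUE
    if (k < n) for (j in ord[(k + 1L):n]) {
      if (alive[j] && boxIoU(boxes[i, ], boxes[j, ]) > nms_iou)
        alive[j] <- FALSE
    }
  }
  proposals[ord[keep[ord]], , drop = FALSE]
}

#' Refine a binary component mask
#'
#' Fills interior holes, then removes connected components smaller than
#' `min_area` pixels.
#'
#' @param mask binary matrix.
#' @param cfg a [maskGenConfig()].
#' @return refined binary matrix.
#' @export
refineMask <- function(mask, cfg = maskGenConfig()) {
  m <- (mask != 0) * 1
  if (cfg$fill_holes)
    m <- as.matrix(EBImage::fillHull(m)) * 1
  lab <- labelComponents8(m)
  if (max(lab) > 0L && cfg$min_area > 0L) {
    area <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(area < cfg$min_area)
    if (length(small)) m[lab %in% small] <- 0
  }
  m
}

# IoU of two binary matrices (same shape); 1 when both are empty.
.maskIoU <- function(a, b) {
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}

#' Propose scored particle masks from a segmentation map
#'
#' The built-in proposer: binarize the probability map, fill holes, remove
#' small artifacts, label 8-connected components, and emit one scored
#' proposal per component.  The `pred_iou` score is a threshold-stability
#' proxy: the mean IoU between the component's footprint at threshold 0.5
#' and its footprints at 0.4 and 0.6 (1 for a hard, binary component).  The
#' confidence score is 100 times the mean probability inside the component.
#' Proposals with confidence at or below `min_confidence` are dropped, and
#' greedy NMS at `nms_iou` removes redundant overlaps.
#'
#' An external promptable mask-generator backend can be slotted in through
#' the same data-frame contract; the built-in proposer keeps the package
#' self-contained (no checkpoint downloads) and is deterministic.
#'
#' @param seg a [SegmentationMask-class] (or a probability matrix).
#' @param cfg a [maskGenConfig()].
#' @return data.frame with columns `bbox_x`, `bbox_y`, `bbox_w`, `bbox_h`,
#'   `pred_iou`, `confidence`, `mask_area`; zero rows if nothing survives.
#' @export
proposeMasks <- function(seg, cfg = maskGenConfig()) {
  v <- if (is(seg, "SegmentationMask")) maskValues(seg) else seg
  stopifnot(is.matrix(v))
  bin <- (v > cfg$binarize_threshold) * 1
  bin <- refineMask(bin, cfg)
  lab <- labelComponents8(bin)
  boxes <- componentBoxes(lab)
  if (nrow(boxes) == 0L) return(emptyProposals())
  lo <- (v > pmax(cfg$binarize_threshold - 0.1, 0)) * 1
  hi <- (v > pmin(cfg$binarize_threshold + 0.1, 1)) * 1
  n <- nrow(boxes)
  pred_iou <- numeric(n); confidence <- numeric(n)
  H <- nrow(v); W <- ncol(v)
  for (k in seq_len(n)) {
    # window = bbox expanded by 2 px; stability measured locally
    r0 <- max(1L, boxes$bbox_y[k] - 1L); r1 <- min(H, boxes$bbox_y[k] + boxes$bbox_h[k] + 2L)
    c0 <- max(1L, boxes$bbox_x[k] - 1L); c1 <- min(W, boxes$bbox_x[k] + boxes$bbox_w[k] + 2L)
    labw <- lab[r0:r1, c0:c1]
    comp <- labw == boxes$label[k]
    # at the looser threshold the footprint may grow into background pixels;
    # pixels already claimed by other components are excluded
    grown <- (lo[r0:r1, c0:c1] == 1) & (labw == 0L | comp)
    shrunk <- (hi[r0:r1, c0:c1] == 1) & comp
    i_lo <- .maskIoU(comp, grown | comp)
    i_hi <- .maskIoU(comp, shrunk)
    pred_iou[k] <- (i_lo + i_hi) / 2
    confidence[k] <- 100 * mean(v[lab == boxes$label[k]])
  }
  out <- data.frame(bbox_x = boxes$bbox_x, bbox_y = boxes$bbox_y,
                    bbox_w = boxes$bbox_w, bbox_h = boxes$bbox_h,
                    pred_iou = clamp(pred_iou, 0, 1),
                    confidence = clamp(confidence, 0, 100),
                    mask_area = boxes$mask_area)
  out <- out[out$confidence > cfg$min_confidence, , drop = FALSE]
  rownames(out) <- NULL
  nmsProposals(out, cfg$nms_iou)
}

emptyProposals <- function() {
  data.frame(bbox_x = numeric(0), bbox_y = numeric(0), bbox_w = numeric(0),
             bbox_h = numeric(0), pred_iou = numeric(0),
             confidence = numeric(0), mask_area = numeric(0))
}

#' Read / write proposals as JSON lines
#'
#' The interchange format between the proposal and postprocessing stages:
#' one JSON object per line with keys `bbox` (`[x, y, w, h]`), `pred_iou`,
#' `confidence`, `area`.
#'
#' @param proposals proposal data.frame.
#' @param path file path.
#' @return `writeProposals`: `path` invisibly; `readProposals`: the
#'   proposal data.frame.
#' @export
writeProposals <- function(proposals, path) {
  lines <- vapply(seq_len(nrow(proposals)), function(k) {
    jsonlite::toJSON(list(
      bbox = as.numeric(proposals[k, c("bbox_x", "bbox_y", "bbox_w",
                                       "bbox_h")]),
      pred_iou = proposals$pred_iou[k],
      confidence = proposals$confidence[k],
      area = proposals$mask_area[k]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeProposals
#' @export
readProposals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(emptyProposals())
  rows <- lapply(lines, jsonlite::fromJSON)
  data.frame(bbox_x = vapply(rows, function(r) r$bbox[1], numeric(1)),
             bbox_y = vapply(rows, function(r) r$bbox[2], numeric(1)),
             bbox_w = vapply(rows, function(r) r$bbox[3], numeric(1)),
             bbox_h = vapply(rows, function(r) r$bbox[4], numeric(1)),
             pred_iou = vapply(rows, function(r) r$pred_iou, numeric(1)),
             confidence = vapply(rows, function(r) r$confidence, numeric(1)),
             mask_area = vapply(rows, function(r) r$area, numeric(1)))
}
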