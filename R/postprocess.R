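# Size-consensus postprocessing of scored mask proposals:
#   1. keep proposals with predicted IoU strictly above a threshold;
#   2. take the mode of the surviving box widths (m_w) and heights (m_h);
#   3. convert (m_w, m_h) to a consensus particle diameter d in
#      original-micrograph pixels, d = sqrt((m_w*o_w/M)^2 + (m_h*o_h/M)^2)
#      with M the model frame size;
#   4. set a size tolerance th as a fraction of the consensus size and keep
#      boxes with  m_w - th/3 < width < m_w + th  (and likewise for height);
#   5. rescale surviving box centers to original-micrograph coordinates.

#' Postprocessing parameters
#'
#' @param iou_min predicted-IoU cut (strictly greater-than; default 0.94).
#' @param th_fraction size-tolerance fraction of the consensus diameter
#'   (default 0.1).
#' @param lower_margin_divisor the lower size margin is `th /
#'   lower_margin_divisor` (default 3): tighter below the mode than above.
#' @param model_size side length of the model frame (default 1024).
#' @param literal_units if TRUE, the size tolerance is computed from the
#'   original-frame diameter `d` instead of the model frame (the literal
#'   mixed-frame reading); default FALSE keeps every comparison in the
#'   model frame.
#' @return A list of class `PostprocessParams`.
#' @export
postprocessParams <- function(iou_min = 0.94, th_fraction = 0.1,
                              lower_margin_divisor = 3, model_size = 1024L,
                              literal_units = FALSE) {
  if (iou_min <= 0 || iou_min >= 1 || th_fraction <= 0 || th_fraction >= 1)
    stopf("iou_min and th_fraction must be in (0, 1)",
          class = "cryopickConfigError")
  if (lower_margin_divisor < 1)
    stopf("lower_margin_divisor must be >= 1", class = "cryopickConfigError")
  structure(list(iou_min = iou_min, th_fraction = th_fraction,
                 lower_margin_divisor = lower_margin_divisor,
                 model_size = as.integer(model_size),
                 literal_units = isTRUE(literal_units)),
            class = c("PostprocessParams", "list"))
}

#' Filter proposals by predicted IoU
#'
#' Keeps proposals whose `pred_iou` is strictly greater than `iou_min`;
#' order is preserved.
#'
#' @param proposals proposal data.frame.
#' @param iou_min threshold (default 0.94).
#' @return filtered data.frame.
#' @export
filterByPredIoU <- function(proposals, iou_min = 0.94) {
  out <- proposals[proposals$pred_iou > iou_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mode of box dimensions
#'
#' Rounds each value to the nearest integer pixel and returns the most
#' frequent; ties are broken by the smallest value.
#'
#' @param values numeric vector of widths or heights (non-empty).
#' @return integer mode.
#' @export
modeDimension <- function(values) {
  if (length(values) == 0L)
    stopf("no particles survived the predicted-IoU filter",
          class = "cryopickEmptyError")
  r <- round(values)
  tab <- table(r)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  as.integer(min(cand))
}

#' Consensus particle diameter in original-micrograph pixels
#'
#' `d = sqrt((m_w * o_w / model_size)^2 + (m_h * o_h / model_size)^2)`:
#' the Euclidean norm of the modal box sides after rescaling each axis
#' from the model frame to the original micrograph.
#'
#' @param m_w,m_h modal box width and height (model-frame pixels).
#' @param o_w,o_h original micrograph width and height.
#' @param model_size model frame side (default 1024).
#' @return diameter `d` in original-micrograph pixels.
#' @export
particleDiameter <- function(m_w, m_h, o_w, o_h, model_size = 1024) {
  if (any(c(m_w, m_h, o_w, o_h, model_size) <= 0))
    stopf("all diameter arguments must be positive",
          class = "cryopickValidationError")
  sqrt((m_w * o_w / model_size)^2 + (m_h * o_h / model_size)^2)
}

#' Size tolerance from the consensus diameter
#'
#' @param d consensus diameter (> 0).
#' @param th_fraction fraction of `d` (default 0.1).
#' @return `th = th_fraction * d`.
#' @export
sizeThreshold <- function(d, th_fraction = 0.1) {
  if (d <= 0)
    stopf("d must be > 0", class = "cryopickValidationError")
  th_fraction * d
}

#' Filter proposals by agreement with the modal box size
#'
#' Keeps proposals with
#' `m_w - th/divisor < width < m_w + th` and
#' `m_h - th/divisor < height < m_h + th` (all strict): the band is
#' tighter below the mode than above it.  `th` must be in the same
#' coordinate frame as the proposal widths/heights.
#'
#' @param proposals proposal data.frame.
#' @param m_w,m_h modal width and height.
#' @param th size tolerance.
#' @param lower_margin_divisor divisor of the lower margin (default 3).
#' @return filtered data.frame.
#' @export
sizeFilter <- function(proposals, m_w, m_h, th, lower_margin_divisor = 3) {
  w <- proposals$bbox_w; h <- proposals$bbox_h
  keep <- (w > m_w - th / lower_margin_divisor) & (w < m_w + th) &
          (h > m_h - th / lower_margin_divisor) & (h < m_h + th)
  out <- proposals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescale a box center from the model frame to the original micrograph
#'
#' `new_x = (bbox_x + bbox_w/2) * o_w / model_size` and likewise for y.
#'
#' @param proposals proposal data.frame (one or more rows).
#' @param o_w,o_h original micrograph width and height.
#' @param model_size model frame side (default 1024).
#' @return data.frame with columns `new_x`, `new_y`.
#' @export
rescaleCenter <- function(proposals, o_w, o_h, model_size = 1024) {
  data.frame(
    new_x = (proposals$bbox_x + proposals$bbox_w / 2) * o_w / model_size,
    new_y = (proposals$bbox_y + proposals$bbox_h / 2) * o_h / model_size)
}

#' Postprocess the proposals of one micrograph into picked particles
#'
#' Composes the predicted-IoU filter, per-axis mode estimation, consensus
#' diameter, size filtering and center rescaling (see the parameter
#' documentation of [postprocessParams()]).  Every emitted particle carries
#' the shared consensus diameter `d`.  If no proposal survives the
#' predicted-IoU filter the result is an empty set (with a warning).
#'
#' @param proposals proposal data.frame from [proposeMasks()].
#' @param o_w,o_h original micrograph width and height in pixels.
#' @param params a [postprocessParams()].
#' @param micrographId label for the resulting [ParticleSet-class].
#' @return A [ParticleSet-class] in original-micrograph coordinates.
#' @export
postprocessMicrograph <- function(proposals, o_w, o_h,
                                  params = postprocessParams(),
                                  micrographId = "micrograph") {
  surv <- filterByPredIoU(proposals, params$iou_min)
  if (nrow(surv) == 0L) {
    warning(sprintf("micrograph %s: no proposals passed the predicted-IoU filter",
                    micrographId))
    return(ParticleSet(micrographId))
  }
  m_w <- modeDimension(surv$bbox_w)
  m_h <- modeDimension(surv$bbox_h)
  d <- particleDiameter(m_w, m_h, o_w, o_h, params$model_size)
  th <- if (params$literal_units) sizeThreshold(d, params$th_fraction)
        else params$th_fraction * sqrt(m_w^2 + m_h^2)
  kept <- sizeFilter(surv, m_w, m_h, th, params$lower_margin_divisor)
  if (nrow(kept) == 0L) {
    warning(sprintf("micrograph %s: no proposals passed the size filter",
                    micrographId))
    return(ParticleSet(micrographId))
  }
  ctr <- rescaleCenter(kept, o_w, o_h, params$model_size)
  ParticleSet(micrographId,
              new_x = clamp(ctr$new_x, 0, o_w - 1e-6),
              new_y = clamp(ctr$new_y, 0, o_h - 1e-6),
              d = rep(d, nrow(kept)))
}
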