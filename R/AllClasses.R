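#' @import methods
NULL

#' Micrograph: a single 2-D cryo-EM exposure
#'
#' Container for one micrograph: a real-valued intensity matrix plus the
#' identity of its source file.  Rows index the y (vertical) axis, columns
#' the x (horizontal) axis, so \code{dim(pixels(x))} is
#' \code{c(height, width)}.  All coordinates handled by the package are
#' 0-based with \code{(x, y) = (column, row)} and the origin at the top-left
#' pixel.
#'
#' @slot pixels numeric matrix of intensities, \code{height x width};
#'   all values finite, both sides at least 64 pixels.
#' @slot sourceId character scalar labelling the micrograph (typically the
#'   file name stem).
#'
#' @seealso [readMRC()], [denoiseMicrograph()]
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", sourceId = "character"),
  validity = function(object) {
    msg <- NULL
    p <- object@pixels
    if (!is.numeric(p))
      msg <- c(msg, "pixels must be a numeric matrix")
    if (any(dim(p) < 64L))
      msg <- c(msg, "micrograph must be at least 64 x 64 pixels")
    if (is.numeric(p) && !all(is.finite(p)))
      msg <- c(msg, "pixels must all be finite")
    if (length(object@sourceId) != 1L || is.na(object@sourceId) ||
        !nzchar(object@sourceId))
      msg <- c(msg, "sourceId must be a non-empty character scalar")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a Micrograph
#'
#' @param pixels numeric matrix, rows = y, columns = x.
#' @param sourceId label for the micrograph (default "micrograph").
#' @return A [Micrograph-class] object.
#' @examples
#' m <- Micrograph(matrix(rnorm(64 * 64), 64, 64), "demo")
#' micrographWidth(m)
#' @export
Micrograph <- function(pixels, sourceId = "micrograph") {
  new("Micrograph", pixels = pixels, sourceId = as.character(sourceId))
}

#' ParticleSet: picked or annotated particle coordinates for one micrograph
#'
#' Holds particle centers and diameters in original-micrograph pixel
#' coordinates (0-based).  The set may be empty.  Each row of
#' \code{particles(x)} has columns \code{new_x}, \code{new_y}, \code{d}.
#'
#' @slot micrographId character scalar, non-empty.
#' @slot particles data.frame with numeric columns \code{new_x},
#'   \code{new_y}, \code{d} (diameter, > 0).
#'
#' @seealso [writeStar()], [readStar()], [readParticleCSV()]
#' @export
setClass("ParticleSet",
  representation(micrographId = "character", particles = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@micrographId) != 1L || !nzchar(object@micrographId))
      msg <- c(msg, "micrographId must be a non-empty character scalar")
    df <- object@particles
    need <- c("new_x", "new_y", "d")
    if (!all(need %in% names(df)))
      msg <- c(msg, sprintf("particles must have columns %s",
                            paste(need, collapse = ", ")))
    else {
      if (nrow(df) > 0 && !all(vapply(df[need], is.numeric, logical(1))))
        msg <- c(msg, "particle columns must be numeric")
      if (nrow(df) > 0 && any(!is.finite(as.matrix(df[need]))))
        msg <- c(msg, "particle coordinates must be finite")
      if (nrow(df) > 0 && any(df$d <= 0))
        msg <- c(msg, "all particle diameters must be > 0")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a ParticleSet
#'
#' @param micrographId label of the owning micrograph.
#' @param new_x,new_y particle center coordinates (original-micrograph
#'   pixels, 0-based).
#' @param d particle diameters in pixels (> 0); recycled to the length of
#'   \code{new_x}.
#' @return A [ParticleSet-class] object.
#' @examples
#' ParticleSet("mic1", new_x = c(10, 50), new_y = c(20, 60), d = 12)
#' @export
ParticleSet <- function(micrographId, new_x = numeric(0),
                        new_y = numeric(0), d = numeric(0)) {
  n <- length(new_x)
  if (n > 0 && length(d) == 1L) d <- rep(d, n)
  df <- data.frame(new_x = as.numeric(new_x), new_y = as.numeric(new_y),
                   d = as.numeric(d))
  new("ParticleSet", micrographId = as.character(micrographId),
      particles = df)
}

#' SegmentationMask: per-pixel particle probability map
#'
#' A square map of per-pixel particle probabilities in \eqn{[0, 1]}, the
#' output of the U-Net and the input to the mask-proposal stage.  Binary
#' ground-truth masks are represented the same way with values in
#' \eqn{\{0, 1\}}.
#'
#' @slot values numeric matrix with all values in \eqn{[0, 1]}.
#' @slot micrographId character scalar.
#'
#' @seealso [predictMask()], [renderMask()], [proposeMasks()]
#' @export
setClass("SegmentationMask",
  representation(values = "matrix", micrographId = "character"),
  validity = function(object) {
    msg <- NULL
    v <- object@values
    if (!is.numeric(v))
      msg <- c(msg, "values must be numeric")
    else if (any(!is.finite(v)) || min(v) < 0 || max(v) > 1)
      msg <- c(msg, "values must lie in [0, 1]")
    if (length(object@micrographId) != 1L)
      msg <- c(msg, "micrographId must be a character scalar")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a SegmentationMask
#'
#' @param values numeric matrix in \eqn{[0,1]}, rows = y, columns = x.
#' @param micrographId label of the source micrograph.
#' @return A [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(values, micrographId = "micrograph") {
  new("SegmentationMask", values = values,
      micrographId = as.character(micrographId))
}
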