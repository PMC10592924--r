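#' Accessors for cryopick classes
#'
#' `pixels()` returns the intensity matrix of a [Micrograph-class];
#' `sourceId()` its label; `micrographWidth()` / `micrographHeight()` its
#' x / y extent in pixels.  `particles()` returns the coordinate data.frame
#' of a [ParticleSet-class]; `micrographId()` its owning micrograph label;
#' `nParticles()` the particle count.  `maskValues()` returns the
#' probability matrix of a [SegmentationMask-class].
#'
#' @param x object to access.
#' @return See details above.
#' @name accessors
#' @aliases pixels sourceId micrographWidth micrographHeight particles
#'   micrographId nParticles maskValues
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("micrographWidth", function(x) standardGeneric("micrographWidth"))
#' @rdname accessors
#' @export
setGeneric("micrographHeight", function(x) standardGeneric("micrographHeight"))
#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setGeneric("micrographId", function(x) standardGeneric("micrographId"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @rdname accessors
setMethod("pixels", "Micrograph", function(x) x@pixels)
#' @rdname accessors
setMethod("sourceId", "Micrograph", function(x) x@sourceId)
#' @rdname accessors
setMethod("micrographWidth", "Micrograph", function(x) ncol(x@pixels))
#' @rdname accessors
setMethod("micrographHeight", "Micrograph", function(x) nrow(x@pixels))
#' @rdname accessors
setMethod("particles", "ParticleSet", function(x) x@particles)
#' @rdname accessors
setMethod("micrographId", "ParticleSet", function(x) x@micrographId)
#' @rdname accessors
setMethod("nParticles", "ParticleSet", function(x) nrow(x@particles))
#' @rdname accessors
setMethod("micrographId", "SegmentationMask", function(x) x@micrographId)
#' @rdname accessors
setMethod("maskValues", "SegmentationMask", function(x) x@values)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph '%s': %d x %d pixels (w x h), range [%.4g, %.4g]\n",
              object@sourceId, ncol(object@pixels), nrow(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ParticleSet", function(object) {
  n <- nrow(object@particles)
  cat(sprintf("ParticleSet '%s': %d particle%s", object@micrographId, n,
              if (n == 1) "" else "s"))
  if (n > 0)
    cat(sprintf(", median diameter %.1f px", stats::median(object@particles$d)))
  cat("\n")
})

setMethod("show", "SegmentationMask", function(object) {
  v <- object@values
  cat(sprintf(
    "SegmentationMask '%s': %d x %d, foreground fraction (>0.5) %.3f\n",
    object@micrographId, ncol(v), nrow(v), mean(v > 0.5)))
})

#' @export
setMethod("length", "ParticleSet", function(x) nrow(x@particles))
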