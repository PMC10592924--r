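# End-to-end picking: read -> denoise -> resize -> segment -> propose ->
# postprocess -> .star, with a machine-readable run report.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the run seed.  Every pipeline
#' constant (predicted-IoU cut 0.94, NMS IoU 0.7, confidence 88.0, size
#' tolerance fraction 0.1, model frame 1024) lives in its stage
#' configuration, never inline.
#'
#' @param denoise a [denoiseConfig()].
#' @param maskgen a [maskGenConfig()].
#' @param postprocess a [postprocessParams()].
#' @param match a [matchConfig()].
#' @param input_size model frame side length (must equal the U-Net's
#'   `input_size`).
#' @param seed integer run seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(denoise = denoiseConfig(),
                           maskgen = maskGenConfig(),
                           postprocess = postprocessParams(),
                           match = matchConfig(),
                           input_size = 1024L, seed = 1L) {
  structure(list(denoise = denoise, maskgen = maskgen,
                 postprocess = postprocess, match = match,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = c("PipelineConfig", "list"))
}

#' Pick particles in one micrograph
#'
#' Runs the full in-memory pipeline on a single [Micrograph-class]:
#' denoise, resize to the model frame, U-Net segmentation, mask proposals,
#' and size-consensus postprocessing back to original-micrograph
#' coordinates.
#'
#' @param m a [Micrograph-class].
#' @param model a trained `UNetModel`.
#' @param config a [pipelineConfig()].
#' @return `list(particles, proposals, counts)`: the picked
#'   [ParticleSet-class], the surviving proposal data.frame, and the
#'   per-stage counts (`proposals`, `post_iou`, `post_size`).
#' @export
pickMicrograph <- function(m, model, config = pipelineConfig()) {
  stopifnot(is(m, "Micrograph"))
  pp <- config$postprocess
  if (config$input_size != model$cfg$input_size)
    stopf("pipeline input_size (%d) != model input_size (%d)",
          config$input_size, model$cfg$input_size,
          class = "cryopickConfigError")
  if (pp$model_size != config$input_size)
    pp$model_size <- config$input_size
  den <- denoiseMicrograph(m, config$denoise)
  resized <- resizeToModel(den, config$input_size)
  seg <- predictMask(model, resized, micrographId = sourceId(m))
  props <- proposeMasks(seg, config$maskgen)
  post_iou <- filterByPredIoU(props, pp$iou_min)
  ps <- withCallingHandlers(
    postprocessMicrograph(props, o_w = micrographWidth(m),
                          o_h = micrographHeight(m), params = pp,
                          micrographId = sourceId(m)),
    warning = function(w) invokeRestart("muffleWarning"))
  list(particles = ps, proposals = props,
       counts = c(proposals = nrow(props), post_iou = nrow(post_iou),
                  post_size = nParticles(ps)))
}

#' Pick particles across a set of micrographs
#'
#' Applies [pickMicrograph()] to every `.mrc` file in a directory (or to a
#' list of [Micrograph-class] objects), optionally writing one `.star`
#' file per micrograph, and returns a run report with per-stage counts.
#' Per-file failures are recorded and skipped; the run fails only if every
#' micrograph fails.
#'
#' @param input directory containing `.mrc` files, or a list of
#'   [Micrograph-class] objects.
#' @param model a trained `UNetModel`.
#' @param config a [pipelineConfig()].
#' @param out_dir if non-NULL, write `<sourceId>.star` files here.
#' @return `list(particle_sets, report)`; `report` is JSON-serialisable
#'   (see [writeRunReport()]).
#' @export
pickParticles <- function(input, model, config = pipelineConfig(),
                          out_dir = NULL) {
  mics <- if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.mrc$", full.names = TRUE))
    if (length(files) == 0L)
      warning(sprintf("no .mrc files found in %s", input))
    files
  } else input
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  entries <- list()
  n_fail <- 0L
  for (k in seq_along(mics)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      m <- if (is.character(mics)) readMRC(mics[[k]]) else mics[[k]]
      out <- pickMicrograph(m, model, config)
      if (nParticles(out$particles) == 0L)
        warning(sprintf("micrograph %s: zero particles picked", sourceId(m)))
      if (!is.null(out_dir))
        writeStar(out$particles,
                  file.path(out_dir, paste0(sourceId(m), ".star")))
      out
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      entries[[k]] <- list(index = k, status = "error",
                           message = conditionMessage(res),
                           seconds = elapsed)
    } else {
      results[[length(results) + 1L]] <- res$particles
      entries[[k]] <- list(index = k,
                           micrograph = micrographId(res$particles),
                           status = "ok",
                           counts = as.list(res$counts),
                           seconds = elapsed)
    }
  }
  if (length(mics) > 0L && n_fail == length(mics))
    stopf("all %d micrographs failed", n_fail, class = "cryopickRunError")
  report <- list(seed = config$seed,
                 n_micrographs = length(mics), n_failed = n_fail,
                 total_particles = sum(vapply(results, nParticles,
                                              integer(1))),
                 micrographs = entries)
  list(particle_sets = results, report = report)
}

#' Write a run report as JSON
#'
#' @param report the `report` element returned by [pickParticles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
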