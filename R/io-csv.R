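#' Read ground-truth particle coordinates from CSV
#'
#' Reads an annotation table with one row per particle: center x, center y
#' and diameter in original-micrograph pixels.  Column names are
#' configurable; the defaults match the common labelled-particle-dataset
#' schema.
#'
#' @param path path to the CSV file.
#' @param x_col,y_col,d_col column names for center x, center y and
#'   diameter.
#' @return A [ParticleSet-class]; `micrographId` is the file name stem.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame("X-Coordinate" = 10, "Y-Coordinate" = 20,
#'                      "Diameter" = 30, check.names = FALSE), f,
#'           row.names = FALSE)
#' readParticleCSV(f)
#' @export
readParticleCSV <- function(path, x_col = "X-Coordinate",
                            y_col = "Y-Coordinate", d_col = "Diameter") {
  if (!file.exists(path))
    stopf("CSV file not found: %s", path, class = "cryopickIOError")
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c(x_col, y_col, d_col))
    if (!col %in% names(df))
      stopf("CSV file %s lacks required column '%s'", path, col,
            class = "cryopickSchemaError")
  if (nrow(df) > 0 && any(!is.finite(df[[d_col]]) | df[[d_col]] <= 0))
    stopf("CSV file %s contains non-positive or non-finite diameters", path,
          class = "cryopickValidationError")
  ParticleSet(tools::file_path_sans_ext(basename(path)),
              new_x = df[[x_col]], new_y = df[[y_col]], d = df[[d_col]])
}

#' Write a ParticleSet to a ground-truth style CSV
#'
#' Inverse of [readParticleCSV()]; used by the synthetic-data generator.
#'
#' @param ps a [ParticleSet-class].
#' @param path output path.
#' @inheritParams readParticleCSV
#' @return `path`, invisibly.
#' @export
writeParticleCSV <- function(ps, path, x_col = "X-Coordinate",
                             y_col = "Y-Coordinate", d_col = "Diameter") {
  stopifnot(is(ps, "ParticleSet"))
  df <- particles(ps)
  out <- data.frame(df$new_x, df$new_y, df$d)
  names(out) <- c(x_col, y_col, d_col)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a particle set as a binary segmentation mask
#'
#' Draws each particle as a filled disc of its annotated diameter, scaling
#' centers and radii from the original micrograph frame `(o_w, o_h)` to a
#' square `out_size x out_size` grid.  Because x and y are scaled
#' independently, discs become ellipses when the micrograph is not square —
#' matching how the model-frame resize treats the image itself.
#'
#' @param ps a [ParticleSet-class] in original-micrograph coordinates.
#' @param o_w,o_h original micrograph width and height in pixels.
#' @param out_size side length of the output mask (default 1024).
#' @return A [SegmentationMask-class] with values in \{0, 1\}.
#' @export
renderMask <- function(ps, o_w, o_h, out_size = 1024L) {
  stopifnot(is(ps, "ParticleSet"), out_size >= 32)
  m <- matrix(0, out_size, out_size)
  df <- particles(ps)
  sx <- out_size / o_w
  sy <- out_size / o_h
  for (k in seq_len(nrow(df))) {
    cx <- df$new_x[k] * sx
    cy <- df$new_y[k] * sy
    rx <- df$d[k] / 2 * sx
    ry <- df$d[k] / 2 * sy
    j0 <- max(1L, floor(cx - rx) ); j1 <- min(out_size, ceiling(cx + rx) + 1)
    i0 <- max(1L, floor(cy - ry) ); i1 <- min(out_size, ceiling(cy + ry) + 1)
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    # pixel (i, j) has 0-based center (j-1, i-1)
    u <- ((jj - 1) - cx) / rx
    v <- ((ii - 1) - cy) / ry
    inside <- outer(v^2, u^2, "+") <= 1
    m[ii, jj][inside] <- 1
  }
  SegmentationMask(m, micrographId(ps))
}
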