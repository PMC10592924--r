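# Minimal RELION-dialect STAR coordinate I/O: a single data block with a
# loop over _rlnCoordinateX / _rlnCoordinateY / _rlnDiameter.

#' Write particle coordinates to a RELION-style .star file
#'
#' Emits a single `data_` block with a `loop_` over the columns
#' `_rlnCoordinateX`, `_rlnCoordinateY`, `_rlnDiameter` (in that order), one
#' row per particle, coordinates printed as decimals with six digits.  An
#' empty [ParticleSet-class] produces a valid file with a header and no rows.
#'
#' @param ps a [ParticleSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readStar()]
#' @export
writeStar <- function(ps, path) {
  stopifnot(is(ps, "ParticleSet"))
  df <- particles(ps)
  lines <- c("", "data_", "", "loop_",
             "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnDiameter #3")
  if (nrow(df) > 0)
    lines <- c(lines, sprintf("%.6f\t%.6f\t%.6f", df$new_x, df$new_y, df$d))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stopf("cannot write STAR file %s: %s", path, conditionMessage(ok),
          class = "cryopickIOError")
  invisible(path)
}

#' Read particle coordinates from a .star file
#'
#' Parses the loop dialect written by [writeStar()] (and RELION autopick
#' coordinate files generally).  `_rlnCoordinateX` and `_rlnCoordinateY` are
#' required; if `_rlnDiameter` is absent, `default_diameter` is used for
#' every particle and a warning is raised.
#'
#' @param path path to the `.star` file.
#' @param default_diameter diameter (pixels) to assign when the file has no
#'   diameter column.
#' @return A [ParticleSet-class]; `micrographId` is the file name stem.
#' @export
readStar <- function(path, default_diameter = 200) {
  if (!file.exists(path))
    stopf("STAR file not found: %s", path, class = "cryopickIOError")
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  loop_at <- which(trimmed == "loop_")
  if (length(loop_at) == 0)
    stopf("malformed STAR file %s: no loop_ block", path,
          class = "cryopickParseError")
  i <- loop_at[1] + 1L
  cols <- character(0)
  while (i <= length(trimmed) && startsWith(trimmed[i], "_")) {
    cols <- c(cols, sub("\\s+#\\d+$", "", trimmed[i]))
    i <- i + 1L
  }
  if (!all(c("_rlnCoordinateX", "_rlnCoordinateY") %in% cols))
    stopf("STAR file %s lacks _rlnCoordinateX/_rlnCoordinateY columns", path,
          class = "cryopickParseError")
  rows <- list()
  while (i <= length(trimmed)) {
    ln <- trimmed[i]
    if (!nzchar(ln) || startsWith(ln, "data_")) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != length(cols))
      stopf("malformed STAR row at line %d of %s: %d fields, expected %d",
            i, path, length(tok), length(cols), class = "cryopickParseError")
    val <- suppressWarnings(as.numeric(tok))
    if (any(is.na(val)))
      stopf("non-numeric STAR value at line %d of %s", i, path,
            class = "cryopickParseError")
    rows[[length(rows) + 1L]] <- val
    i <- i + 1L
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(cols))
  colnames(mat) <- cols
  x <- mat[, "_rlnCoordinateX"]
  y <- mat[, "_rlnCoordinateY"]
  if ("_rlnDiameter" %in% cols) {
    d <- mat[, "_rlnDiameter"]
  } else {
    if (nrow(mat) > 0)
      warning(sprintf("STAR file %s has no _rlnDiameter column; using default %g",
                      path, default_diameter))
    d <- rep(default_diameter, nrow(mat))
  }
  ParticleSet(tools::file_path_sans_ext(basename(path)),
              new_x = x, new_y = y, d = d)
}
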