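# MRC2014 single-image I/O.  Only image modes are supported:
#   mode 0 = int8, mode 1 = int16, mode 2 = float32.
# Data are stored x-fastest; in memory the package keeps [row = y, col = x].

#' Read a single-image MRC micrograph
#'
#' Parses an MRC2014 file (modes 0, 1, 2) into a [Micrograph-class].  Pixel
#' values are returned in native units as doubles; no rescaling is applied.
#' Multi-section files (volumes / movie stacks, `nz > 1`) are rejected.
#'
#' @param path path to the `.mrc` file.
#' @return A [Micrograph-class]; `sourceId` is the file name stem.
#' @examples
#' mrc <- tempfile(fileext = ".mrc")
#' writeMRC(Micrograph(matrix(rnorm(64^2), 64, 64), "demo"), mrc)
#' readMRC(mrc)
#' @seealso [writeMRC()]
#' @export
readMRC <- function(path) {
  if (!file.exists(path))
    stopf("MRC file not found: %s", path, class = "cryopickIOError")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L)
    stopf("truncated MRC header in %s (%d bytes)", path, length(hdr),
          class = "cryopickFormatError")
  int3 <- function(off, endian) readBin(hdr[(off + 1):(off + 12)], "integer",
                                        n = 3L, size = 4L, endian = endian)
  endian <- "little"
  dims <- int3(0L, endian)
  if (any(dims <= 0L) || any(dims > 1e6)) {
    endian <- "big"
    dims <- int3(0L, endian)
  }
  if (any(dims <= 0L) || any(dims > 1e6))
    stopf("not a valid MRC file (implausible dimensions): %s", path,
          class = "cryopickFormatError")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mode <- readBin(hdr[13:16], "integer", size = 4L, endian = endian)
  nsymbt <- readBin(hdr[93:96], "integer", size = 4L, endian = endian)
  if (nz != 1L)
    stopf("MRC file %s has 3 axes (nz = %d); only single-image files are supported",
          path, nz, class = "cryopickFormatError")
  if (!mode %in% c(0L, 1L, 2L))
    stopf("unsupported MRC mode %d in %s (modes 0/1/2 supported)", mode, path,
          class = "cryopickFormatError")
  if (nsymbt < 0L || nsymbt > 1e7)
    stopf("corrupt MRC extended header size in %s", path,
          class = "cryopickFormatError")
  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))
  n <- as.numeric(nx) * ny
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = endian))
  if (length(vals) < n)
    stopf("truncated MRC data in %s: expected %d values, read %d", path, n,
          length(vals), class = "cryopickFormatError")
  # x fastest on disk -> fill an (nx, ny) matrix, transpose to [y, x]
  px <- t(matrix(vals, nrow = nx, ncol = ny))
  Micrograph(px, sourceId = tools::file_path_sans_ext(basename(path)))
}

#' Write a Micrograph to an MRC2014 file
#'
#' Writes mode-2 (float32) little-endian MRC with a minimal standard header.
#'
#' @param m a [Micrograph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readMRC()]
#' @export
writeMRC <- function(m, path) {
  stopifnot(is(m, "Micrograph"))
  px <- pixels(m)
  h <- nrow(px); w <- ncol(px)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stopf("cannot open %s for writing: %s", path, conditionMessage(e),
          class = "cryopickIOError"))
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wInt(c(w, h, 1L))          # nx ny nz
  wInt(2L)                   # mode 2 = float32
  wInt(c(0L, 0L, 0L))        # nxstart nystart nzstart
  wInt(c(w, h, 1L))          # mx my mz
  wFlt(c(w, h, 1))           # cell dimensions (1 A/px nominal)
  wFlt(c(90, 90, 90))        # cell angles
  wInt(c(1L, 2L, 3L))        # mapc mapr maps
  wFlt(c(min(px), max(px), mean(px)))  # dmin dmax dmean
  wInt(0L)                   # ispg
  wInt(0L)                   # nsymbt
  writeBin(raw(100L), con)   # extra
  wFlt(c(0, 0, 0))           # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(as.vector(px)))                    # rms
  wInt(0L)                   # nlabl
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")
  invisible(path)
}
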