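# Minimal MRC2014 reader/writer for single 2D maps (modes 0/1/2).
# The MRC fast axis (x) maps to matrix columns; the package stores images
# as matrix[row, col] so the file is (de)serialized row by row.

mrcModes <- c(`0` = "int8", `1` = "int16", `2` = "float32")

#' Read a single-image MRC map
#'
#' Supports MRC2014 modes 0 (signed 8-bit), 1 (signed 16-bit) and 2 (32-bit
#' float), little- or big-endian. 3D stacks (\code{nz > 1}) are rejected:
#' picking operates per micrograph. The pixel size is taken from the cell
#' dimension divided by the grid size (\code{xlen/mx}) when the header
#' carries one.
#'
#' @param path file path.
#' @return A \linkS4class{Micrograph}.
#' @keywords internal
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdrRaw <- readBin(con, "raw", n = 1024L)
  if (length(hdrRaw) < 1024L)
    stop("unreadable MRC file (truncated header): ", path, call. = FALSE)
  readHdr <- function(endian) {
    list(dims = readBin(hdrRaw[1:12], "integer", n = 3L, size = 4L,
                        endian = endian),
         mode = readBin(hdrRaw[13:16], "integer", n = 1L, size = 4L,
                        endian = endian),
         mgrid = readBin(hdrRaw[29:40], "integer", n = 3L, size = 4L,
                         endian = endian),
         cella = readBin(hdrRaw[41:52], "numeric", n = 3L, size = 4L,
                         endian = endian))
  }
  endian <- "little"
  h <- readHdr(endian)
  if (any(h$dims <= 0L) || any(h$dims > 1e6L)) {
    endian <- "big"
    h <- readHdr(endian)
  }
  if (any(h$dims <= 0L) || any(h$dims > 1e6L))
    stop("unreadable MRC file (implausible dimensions): ", path,
         call. = FALSE)
  if (h$dims[3] > 1L)
    stop("unsupported format: 3D MRC stack (nz = ", h$dims[3], ") in ",
         path, call. = FALSE)
  modeName <- mrcModes[as.character(h$mode)]
  if (is.na(modeName))
    stop("unsupported MRC mode ", h$mode, " in ", path, call. = FALSE)
  nx <- h$dims[1]; ny <- h$dims[2]
  n <- nx * ny
  vals <- switch(modeName,
    int8 = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                   endian = endian),
    int16 = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                    endian = endian),
    float32 = readBin(con, "numeric", n = n, size = 4L, endian = endian))
  if (length(vals) < n)
    stop("unreadable MRC file (truncated data): ", path, call. = FALSE)
  # file order: x fastest -> fill a (nx x ny) matrix column-wise, transpose
  pix <- t(matrix(as.numeric(vals), nrow = nx, ncol = ny))
  px <- NA_real_
  if (h$mgrid[1] > 0L && is.finite(h$cella[1]) && h$cella[1] > 0)
    px <- h$cella[1] / h$mgrid[1]
  Micrograph(pix, pixelSize = px, sourcePath = path)
}

#' Write a 2D image as an MRC2014 map (mode 2, little-endian)
#'
#' @param micrograph a \linkS4class{Micrograph} or numeric matrix.
#' @param path output path.
#' @param pixelSize Angstrom/pixel written to the cell header; defaults to
#'   the micrograph's own pixel size when available.
#' @return Invisibly, \code{path}.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' writeMRC(Micrograph(matrix(1, 32, 32)), f)
#' readMicrograph(f)
#' @export
writeMRC <- function(micrograph, path, pixelSize = NULL) {
  pix <- if (is(micrograph, "Micrograph")) micrograph@pixels
         else as.matrix(micrograph)
  if (is.null(pixelSize))
    pixelSize <- if (is(micrograph, "Micrograph")) micrograph@pixelSize
                 else NA_real_
  ny <- nrow(pix); nx <- ncol(pix)
  con <- tryCatch(file(path, "wb"),
                  error = function(e)
                    stop("cannot write MRC file: ", path, call. = FALSE))
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  cell <- if (is.finite(pixelSize)) pixelSize else 0
  wInt(c(nx, ny, 1L))                     # NX NY NZ
  wInt(2L)                                # MODE 2 = float32
  wInt(c(0L, 0L, 0L))                     # N*START
  wInt(c(nx, ny, 1L))                     # MX MY MZ
  wFlt(c(cell * nx, cell * ny, cell))     # CELLA
  wFlt(c(90, 90, 90))                     # CELLB
  wInt(c(1L, 2L, 3L))                     # MAPC MAPR MAPS
  wFlt(c(min(pix), max(pix), mean(pix)))  # DMIN DMAX DMEAN
  wInt(c(0L, 0L))                         # ISPG NSYMBT
  wInt(rep(0L, 3))                        # EXTRA (words 25-27)
  wInt(20140L)                            # NVERSION (word 28)
  wInt(rep(0L, 21))                       # EXTRA (words 29-49)
  wFlt(c(0, 0, 0))                        # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)   # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST
  wFlt(stats::sd(pix))                    # RMS
  wInt(0L)                                # NLABL
  writeBin(raw(800L), con)                # labels
  writeBin(as.numeric(t(pix)), con, size = 4L, endian = "little")
  invisible(path)
}
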