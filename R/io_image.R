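#' Read a micrograph from MRC, TIFF or PNG
#'
#' Dispatches on the file extension: \code{.mrc}/\code{.map} go through the
#' MRC2014 reader, \code{.tif}/\code{.tiff} through \pkg{tiff} and
#' \code{.png} through \pkg{png}. Integer images keep their native integer
#' scale (an 8-bit PNG with values 0 and 255 yields pixels 0.0 and 255.0 —
#' no silent rescale to [0,1]); multi-channel images are collapsed to one
#' channel by the per-pixel mean. Non-finite pixels are replaced by the
#' image median with a warning.
#'
#' @param path file path.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' writeMRC(matrix(rnorm(24 * 24), 24), f, pixelSize = 1.07)
#' pixelSize(readMicrograph(f))
#' @export
readMicrograph <- function(path) {
  if (!file.exists(path))
    stop("cannot read micrograph, no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs", "map")) return(readMRC(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    x * (2^depth - 1)   # undo readPNG's [0,1] normalization
  } else {
    stop("unsupported micrograph format '", ext, "': ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  Micrograph(img, sourcePath = path)
}

#' Write a binary or probability mask as an 8-bit PNG
#'
#' @param mask a \linkS4class{SegmentationMask} or numeric matrix in [0,1].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMaskPNG <- function(mask, path) {
  v <- if (is(mask, "SegmentationMask")) mask@values else as.matrix(mask)
  png::writePNG(pmin(pmax(v, 0), 1), path)
  invisible(path)
}
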