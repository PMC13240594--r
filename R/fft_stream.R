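#' Gaussian high-pass FFT filter
#'
#' Filters an image in the Fourier domain with a Gaussian high-pass
#' transfer function \code{H(f) = 1 - exp(-f^2 / (2 fc^2))}, where
#' \code{fc = cutoffFraction * Nyquist}. The DC gain is exactly zero, so a
#' constant image maps to (numerically) zero and any output has zero mean.
#' The Gaussian transition avoids the ringing of an ideal brick-wall
#' filter.
#'
#' @param image numeric matrix with finite entries.
#' @param cutoffFraction high-pass cutoff as a fraction of the Nyquist
#'   frequency, in (0, 1). Default 0.25.
#' @return Real matrix of the same shape, emphasizing particle edges over
#'   slowly varying background.
#' @examples
#' out <- highpassFilter(matrix(rnorm(64 * 64), 64))
#' abs(sum(out)) < 1e-6 * 64 * 64
#' @export
highpassFilter <- function(image, cutoffFraction = 0.25) {
  image <- as.matrix(image)
  if (any(!is.finite(image)))
    stop("highpassFilter requires finite input", call. = FALSE)
  if (!is.finite(cutoffFraction) || cutoffFraction <= 0 ||
      cutoffFraction >= 1)
    stop("cutoffFraction must lie in (0, 1)", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  freqAxis <- function(n) {
    k <- seq_len(n) - 1L
    ifelse(k <= n %/% 2, k, k - n) / n
  }
  fy <- freqAxis(nr)
  fx <- freqAxis(nc)
  f2 <- outer(fy^2, fx^2, "+")
  fc <- cutoffFraction * 0.5
  H <- 1 - exp(-f2 / (2 * fc^2))
  H[1, 1] <- 0
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / (nr * nc)
}

#' Per-stage high-pass FFT streams
#'
#' Computes the high-pass filtered micrograph once at full resolution, then
#' average-pools it to each encoder stage's spatial grid and standardizes
#' each stage stream to zero mean / unit variance (an all-constant stream
#' maps to zeros). These streams are the frequency-domain input of every
#' adapter in the corresponding stage.
#'
#' @param micrograph a \linkS4class{Micrograph} or numeric matrix.
#' @param stageShapes list of integer(2) per-stage spatial shapes, as
#'   reported by \code{\link{encoderStageShapes}}.
#' @param cutoffFraction see \code{\link{highpassFilter}}.
#' @return List of matrices, one per stage shape.
#' @export
prepareFFTStream <- function(micrograph, stageShapes,
                             cutoffFraction = 0.25) {
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels
         else as.matrix(micrograph)
  hp <- highpassFilter(img, cutoffFraction)
  lapply(stageShapes, function(sh) {
    fr <- nrow(hp) / sh[1]
    fc <- ncol(hp) / sh[2]
    if (fr != round(fr) || fc != round(fc) || fr < 1 || fc < 1)
      contractError("stage shape (", sh[1], ", ", sh[2],
                    ") is not an integer downsampling of the image (",
                    nrow(hp), ", ", ncol(hp), ")")
    standardizeMatrix(blockMeanPool(hp, as.integer(fr), as.integer(fc)))
  })
}
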