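# Synthetic low-SNR micrographs: soft-edged disks on a zero-mean background
# with additive Gaussian noise, exact ground-truth masks and coordinates.
# These emulate the dominant difficulty of real micrographs (low contrast,
# crowding) without CTF or ice/carbon artifacts.

#' Specification of a synthetic micrograph
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: 128 x 128 px fields of 16 px particles at SNR 4,
#' non-overlapping with a minimum center separation of 1.5 diameters.
#' SNR is defined operationally as particle contrast amplitude squared over
#' noise variance, so noise is drawn with standard deviation
#' \code{amplitude / sqrt(snr)}.
#'
#' @param imageShape integer(2) (height, width) in pixels.
#' @param nParticles number of particles (>= 0).
#' @param diameterPx particle diameter in pixels (>= 3).
#' @param diameterJitter fractional uniform jitter on the diameter.
#' @param snr signal-to-noise ratio (> 0), amplitude^2 / noise variance.
#' @param minSeparation minimum center-to-center distance in pixels; may be
#'   smaller than the diameter to force overlaps when \code{allowOverlap}.
#' @param allowOverlap if \code{FALSE} the effective separation is at least
#'   one diameter, so disks never overlap.
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @return A validated list of class \code{"SyntheticSpec"}.
#' @examples
#' spec <- syntheticSpec(nParticles = 5, seed = 1)
#' out <- simulateMicrograph(spec)
#' nParticles(out$particles)
#' @export
syntheticSpec <- function(imageShape = c(128L, 128L), nParticles = 12L,
                          diameterPx = 16, diameterJitter = 0, snr = 4,
                          minSeparation = 1.5 * diameterPx,
                          allowOverlap = FALSE, seed = 1L) {
  spec <- list(imageShape = as.integer(imageShape),
               nParticles = as.integer(nParticles),
               diameterPx = as.numeric(diameterPx),
               diameterJitter = as.numeric(diameterJitter),
               snr = as.numeric(snr),
               minSeparation = as.numeric(minSeparation),
               allowOverlap = isTRUE(allowOverlap),
               seed = as.integer(seed))
  if (length(spec$imageShape) != 2L || any(spec$imageShape < 16L))
    stop("imageShape must be two integers >= 16", call. = FALSE)
  if (spec$nParticles < 0L) stop("nParticles must be >= 0", call. = FALSE)
  if (spec$diameterPx < 3) stop("diameterPx must be >= 3", call. = FALSE)
  if (!is.finite(spec$snr) || spec$snr <= 0)
    stop("snr must be > 0", call. = FALSE)
  if (spec$diameterJitter < 0 || spec$diameterJitter >= 1)
    stop("diameterJitter must lie in [0, 1)", call. = FALSE)
  class(spec) <- "SyntheticSpec"
  spec
}

# Render one soft disk (1 px cosine-tapered edge) and its hard raster mask.
# cx, cy are 0-based pixel-center coordinates.
renderDisk <- function(shape, cx, cy, diameter, amplitude = 1) {
  R <- diameter / 2
  r0 <- max(1L, floor(cy - R - 1) + 1L)
  r1 <- min(shape[1], ceiling(cy + R + 1) + 1L)
  c0 <- max(1L, floor(cx - R - 1) + 1L)
  c1 <- min(shape[2], ceiling(cx + R + 1) + 1L)
  rows <- r0:r1
  cols <- c0:c1
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  rr <- sqrt(outer(dy^2, dx^2, "+"))
  soft <- matrix(0, length(rows), length(cols))
  soft[rr <= R - 0.5] <- 1
  edge <- rr > R - 0.5 & rr < R + 0.5
  soft[edge] <- 0.5 * (1 + cos(pi * (rr[edge] - (R - 0.5))))
  list(rows = rows, cols = cols, soft = amplitude * soft, hard = rr <= R)
}

placeCenters <- function(spec) {
  R <- spec$diameterPx / 2
  h <- spec$imageShape[1]; w <- spec$imageShape[2]
  lo <- R; hiX <- w - 1 - R; hiY <- h - 1 - R
  if (hiX <= lo || hiY <= lo)
    stop("image too small for the requested particle diameter",
         call. = FALSE)
  sep <- if (spec$allowOverlap) spec$minSeparation
         else max(spec$minSeparation, spec$diameterPx)
  xs <- numeric(0); ys <- numeric(0)
  maxTries <- 200L * max(1L, spec$nParticles)
  tries <- 0L
  while (length(xs) < spec$nParticles && tries < maxTries) {
    tries <- tries + 1L
    x <- runif(1, lo, hiX)
    y <- runif(1, lo, hiY)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < spec$nParticles)
    stop("placement capacity exceeded: placed ", length(xs), " of ",
         spec$nParticles, " particles at min separation ", sep,
         call. = FALSE)
  list(x = xs, y = ys)
}

#' Simulate one synthetic micrograph with exact ground truth
#'
#' Particles are rendered as soft-edged disks of amplitude 1 on a zero
#' background; i.i.d. Gaussian noise with variance \code{1/snr} is added
#' everywhere. The ground-truth mask is the union of the hard rasterized
#' disks (pixel centers within one radius of a particle center) and the
#' ground-truth \linkS4class{ParticleSet} holds the exact continuous
#' centers and diameters.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with elements \code{micrograph}, \code{mask} (binary) and
#'   \code{particles} (ground truth).
#' @export
simulateMicrograph <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    shape <- spec$imageShape
    img <- matrix(0, shape[1], shape[2])
    msk <- matrix(0, shape[1], shape[2])
    if (spec$nParticles > 0L) {
      ctr <- placeCenters(spec)
      dvec <- spec$diameterPx *
        (1 + runif(spec$nParticles, -spec$diameterJitter,
                   spec$diameterJitter))
      for (k in seq_len(spec$nParticles)) {
        dd <- renderDisk(shape, ctr$x[k], ctr$y[k], dvec[k])
        img[dd$rows, dd$cols] <- pmax(img[dd$rows, dd$cols], dd$soft)
        msk[dd$rows, dd$cols] <- pmax(msk[dd$rows, dd$cols],
                                      as.numeric(dd$hard))
      }
    } else {
      ctr <- list(x = numeric(), y = numeric())
      dvec <- numeric()
    }
    noise <- matrix(rnorm(prod(shape), sd = 1 / sqrt(spec$snr)),
                    shape[1], shape[2])
    list(micrograph = Micrograph(img + noise),
         mask = SegmentationMask(msk, kind = "binary"),
         particles = ParticleSet(x = ctr$x, y = ctr$y, diameter = dvec,
                                 referenceShape = shape,
                                 provenance = "ground_truth"))
  })
}

#' Simulate a pair of overlapping particles
#'
#' Two disks of equal diameter with centers \code{centerGap} pixels apart
#' (horizontally, centered in the field). Because \code{centerGap <
#' diameterPx} the disks overlap and the ground-truth mask is a single
#' connected component — the canonical fixture for watershed splitting.
#'
#' @param diameterPx disk diameter in pixels (>= 3).
#' @param centerGap center-to-center distance, \code{0 < centerGap <
#'   diameterPx}.
#' @param seed integer RNG seed (noise only).
#' @param snr signal-to-noise ratio of the rendered micrograph.
#' @return list with elements \code{micrograph}, \code{mask},
#'   \code{particles} (two entries).
#' @export
simulateOverlappingPair <- function(diameterPx, centerGap, seed = 1L,
                                    snr = 4) {
  if (!(centerGap > 0 && centerGap < diameterPx))
    stop("centerGap must satisfy 0 < centerGap < diameterPx ",
         "(got gap ", centerGap, ", diameter ", diameterPx, ")",
         call. = FALSE)
  side <- max(32L, as.integer(ceiling(2.5 * diameterPx + centerGap)))
  shape <- c(side, side)
  cy <- (side - 1) / 2
  cx <- c((side - 1) / 2 - centerGap / 2, (side - 1) / 2 + centerGap / 2)
  withSeed(seed, {
    img <- matrix(0, side, side)
    msk <- matrix(0, side, side)
    for (k in 1:2) {
      dd <- renderDisk(shape, cx[k], cy, diameterPx)
      img[dd$rows, dd$cols] <- pmax(img[dd$rows, dd$cols], dd$soft)
      msk[dd$rows, dd$cols] <- pmax(msk[dd$rows, dd$cols],
                                    as.numeric(dd$hard))
    }
    img <- img + matrix(rnorm(side * side, sd = 1 / sqrt(snr)), side, side)
    list(micrograph = Micrograph(img),
         mask = SegmentationMask(msk, kind = "binary"),
         particles = ParticleSet(x = cx, y = rep(cy, 2),
                                 diameter = diameterPx,
                                 referenceShape = shape,
                                 provenance = "ground_truth"))
  })
}

#' Simulate a K-shot annotated dataset
#'
#' Draws \code{K} independent micrographs from \code{spec} using the seed
#' schedule \code{spec$seed + 0 .. K-1}, so the first items of datasets
#' sharing a base seed coincide.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param K shot count (>= 1).
#' @return A \linkS4class{FewShotDataset}.
#' @export
simulateFewShotDataset <- function(spec, K) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1", call. = FALSE)
  items <- lapply(seq_len(K) - 1L, function(o) {
    s <- spec
    s$seed <- spec$seed + o
    simulateMicrograph(s)
  })
  FewShotDataset(items)
}
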