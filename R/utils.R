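# Internal numeric helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# exact GELU, x * Phi(x), and its derivative
gelu <- function(x) x * stats::pnorm(x)
geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# 1D bilinear interpolation matrix (nOut x nIn), half-pixel convention
bilinearMatrix <- function(nOut, nIn) {
  B <- matrix(0, nOut, nIn)
  if (nIn == 1L) { B[, 1] <- 1; return(B) }
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  src <- pmin(pmax(src, 0), nIn - 1)
  lo <- floor(src)
  w <- src - lo
  hi <- pmin(lo + 1, nIn - 1)
  for (i in seq_len(nOut)) {
    B[i, lo[i] + 1] <- B[i, lo[i] + 1] + (1 - w[i])
    B[i, hi[i] + 1] <- B[i, hi[i] + 1] + w[i]
  }
  B
}

# Bilinear resize of a matrix to outShape = c(rows, cols)
resizeBilinear <- function(m, outShape) {
  if (identical(dim(m), as.integer(outShape))) return(m)
  Br <- bilinearMatrix(outShape[1], nrow(m))
  Bc <- bilinearMatrix(outShape[2], ncol(m))
  Br %*% m %*% t(Bc)
}

# Nearest-neighbour resize (label preserving), half-pixel convention
resizeNearest <- function(m, outShape) {
  if (identical(dim(m), as.integer(outShape))) return(m)
  ri <- pmin(pmax(floor((seq_len(outShape[1]) - 0.5) * nrow(m) /
                          outShape[1]) + 1, 1), nrow(m))
  ci <- pmin(pmax(floor((seq_len(outShape[2]) - 0.5) * ncol(m) /
                          outShape[2]) + 1, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Mean-pool a matrix by integer block factors
blockMeanPool <- function(m, fr, fc = fr) {
  nr <- nrow(m) %/% fr
  nc <- ncol(m) %/% fc
  stopifnot(nr * fr == nrow(m), nc * fc == ncol(m))
  a <- array(m, dim = c(fr, nr, fc, nc))
  out <- apply(a, c(2, 4), mean)
  matrix(out, nr, nc)
}

# zero-mean / unit-variance; all-constant input maps to zeros
standardizeMatrix <- function(m) {
  s <- stats::sd(m)
  if (!is.finite(s) || s < 1e-12) return(m * 0)
  (m - mean(m)) / s
}

# Separable Gaussian smoothing with edge replication
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x, along) {
    n <- if (along == 1) nrow(x) else ncol(x)
    out <- x * 0
    for (o in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1] *
        (if (along == 1) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    out
  }
  smooth1(smooth1(m, 1), 2)
}

# Grayscale maximum filter over a (2r+1) square window, edge replication
maxFilter <- function(m, r) {
  shiftMax <- function(x, along) {
    n <- if (along == 1) nrow(x) else ncol(x)
    out <- x
    for (o in seq(-r, r)) {
      if (o == 0) next
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- pmax(out,
        if (along == 1) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    out
  }
  shiftMax(shiftMax(m, 1), 2)
}

# Stage-qualified error helpers
contractError <- function(...) stop(..., call. = FALSE)
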