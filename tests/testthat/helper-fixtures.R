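# Shared fixtures and independent oracles used across the suite.

# small encoder/adapter pair for fast forward/backward tests
tinyEncoder <- function(seed = 3) {
  buildSurrogateEncoder(c(8, 16, 32, 64), c(1, 1, 2, 1), patchStride = 4,
                        seed = seed)
}

tinyAdapters <- function(seed = 5, reduction = 4) {
  buildAdapterStack(adapterStackConfig(stageDims = c(8, 16, 32, 64),
                                       stageDepths = c(1, 1, 2, 1),
                                       reduction = reduction, seed = seed))
}

# independent high-pass oracle: explicit frequency grid, Gaussian mask,
# inverse FFT (written without reference to the implementation)
oracleHighpass <- function(img, cutoff = 0.25) {
  nr <- nrow(img); nc <- ncol(img)
  H <- matrix(0, nr, nc)
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      fy <- (a - 1); if (fy > nr / 2) fy <- fy - nr
      fx <- (b - 1); if (fx > nc / 2) fx <- fx - nc
      f2 <- (fy / nr)^2 + (fx / nc)^2
      H[a, b] <- 1 - exp(-f2 / (2 * (cutoff * 0.5)^2))
    }
  }
  H[1, 1] <- 0
  Re(fft(fft(img) * H, inverse = TRUE)) / (nr * nc)
}

# independent maximum-cardinality bipartite matching (Kuhn's algorithm)
oracleMaxMatching <- function(px, py, gx, gy, radius) {
  nP <- length(px); nG <- length(gx)
  if (!nP || !nG) return(0L)
  adj <- lapply(seq_len(nP), function(i)
    which((px[i] - gx)^2 + (py[i] - gy)^2 <= radius^2))
  matchG <- integer(nG)
  visited <- logical(nG)
  aug <- function(i) {
    for (j in adj[[i]]) {
      if (!visited[j]) {
        visited[j] <<- TRUE
        if (matchG[j] == 0L || aug(matchG[j])) {
          matchG[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(nP)) {
    visited[] <- FALSE
    if (aug(i)) cnt <- cnt + 1L
  }
  cnt
}

# brute-force nearest-background distance for a binary matrix
oracleDistance <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  bg <- which(v == 0, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  fg <- which(v == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1], fg[k, 2]] <-
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  }
  out
}

# brute-force regional maxima (strictly >= all 8 neighbours, positive)
oracleRegionalMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (m[r, c] <= 0) next
      nb <- m[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      if (m[r, c] >= max(nb)) out[r, c] <- TRUE
    }
  }
  out
}

# rasterize one particle set as a logical disk-union matrix (independent of
# the package's rasterizer)
oracleRaster <- function(x, y, d, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_along(x)) {
    for (r in seq_len(shape[1])) {
      for (c in seq_len(shape[2])) {
        if ((c - 1 - x[k])^2 + (r - 1 - y[k])^2 <= (d[k] / 2)^2)
          out[r, c] <- TRUE
      }
    }
  }
  out
}

# pooled picking metrics of a trained model over held-out micrographs
pooledHeldOutMetrics <- function(model, spec, nHeld, seedOffset = 1000,
                                 diameter = 16) {
  cfg <- postprocessConfig(expectedDiameterPx = diameter)
  tp <- fp <- fn <- 0
  for (k in seq_len(nHeld)) {
    s2 <- spec
    s2$seed <- spec$seed + seedOffset + k
    held <- simulateMicrograph(s2)
    prob <- predictMask(model, held$micrograph)
    ps <- masksToParticles(prob, cfg)
    m <- matchCounts(matchParticles(ps, held$particles,
                                    matchRadius = diameter / 2))
    tp <- tp + m[["tp"]]; fp <- fp + m[["fp"]]; fn <- fn + m[["fn"]]
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}
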