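# Mask-to-coordinates localization: binarize, Euclidean distance transform,
# multi-scale peak detection, marker-controlled watershed, geometric
# (area/circularity) filtering, dual-pass recovery of closely packed
# particles, and deduplication. All thresholds are configuration with
# documented defaults; tie-breaks are total orders so the pipeline is
# deterministic.

#' Postprocessing configuration
#'
#' @param expectedDiameterPx expected particle diameter in pixels; anchors
#'   area bounds, peak spacing and deduplication radius.
#' @param threshold binarization threshold on mask probability (strict
#'   \code{>}), default 0.5.
#' @param areaRange numeric(2) multiples of the expected disk area
#'   \code{pi * (d/2)^2} that a region may occupy, default c(0.3, 3).
#' @param minCircularity minimum \code{4 * pi * A / P^2}, default 0.6
#'   (1 for an ideal disk).
#' @param peakScales Gaussian smoothing sigmas (px) for multi-scale peak
#'   detection, default c(1, 2, 4); finer scales take precedence.
#' @param minPeakDistanceFrac minimum peak spacing as a fraction of the
#'   expected diameter, default 0.5.
#' @param minSeparationFrac deduplication radius as a fraction of the
#'   expected diameter, default 0.6.
#' @param dualPass run the second (recovery) pass, default TRUE.
#' @param dropBorder drop regions touching the image border, default FALSE.
#' @return A validated list of class \code{"PostprocessConfig"}.
#' @export
postprocessConfig <- function(expectedDiameterPx, threshold = 0.5,
                              areaRange = c(0.3, 3.0),
                              minCircularity = 0.6,
                              peakScales = c(1, 2, 4),
                              minPeakDistanceFrac = 0.5,
                              minSeparationFrac = 0.6, dualPass = TRUE,
                              dropBorder = FALSE) {
  cfg <- list(expectedDiameterPx = as.numeric(expectedDiameterPx),
              threshold = as.numeric(threshold),
              areaRange = as.numeric(areaRange),
              minCircularity = as.numeric(minCircularity),
              peakScales = sort(as.numeric(peakScales)),
              minPeakDistanceFrac = as.numeric(minPeakDistanceFrac),
              minSeparationFrac = as.numeric(minSeparationFrac),
              dualPass = isTRUE(dualPass), dropBorder = isTRUE(dropBorder))
  if (!is.finite(cfg$expectedDiameterPx) || cfg$expectedDiameterPx <= 0)
    stop("expectedDiameterPx must be > 0", call. = FALSE)
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (length(cfg$areaRange) != 2L || cfg$areaRange[1] >= cfg$areaRange[2])
    stop("areaRange must satisfy min < max", call. = FALSE)
  if (any(cfg$peakScales <= 0))
    stop("peak scales must be > 0", call. = FALSE)
  if (cfg$minCircularity < 0 || cfg$minCircularity > 1)
    stop("minCircularity must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "PostprocessConfig"
  cfg
}

#' Binarize a probability mask
#'
#' Foreground where probability is strictly greater than the threshold.
#'
#' @param mask a probability \linkS4class{SegmentationMask} (a binary mask
#'   passes through thresholding unchanged).
#' @param threshold numeric in [0, 1).
#' @return A binary \linkS4class{SegmentationMask}.
#' @export
binarizeMask <- function(mask, threshold = 0.5) {
  v <- if (is(mask, "SegmentationMask")) mask@values else as.matrix(mask)
  SegmentationMask((v > threshold) * 1, kind = "binary")
}

#' Euclidean distance transform of a binary mask
#'
#' Distance from each foreground pixel to the nearest background pixel
#' (zero on background). Delegates to \code{EBImage::distmap}.
#'
#' @param binary a binary \linkS4class{SegmentationMask} or 0/1 matrix.
#' @return numeric matrix of distances.
#' @export
distanceMap <- function(binary) {
  v <- if (is(binary, "SegmentationMask")) binary@values
       else as.matrix(binary)
  if (!all(v %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  if (all(v == 0)) return(v * 0)
  m <- EBImage::imageData(EBImage::distmap(v, metric = "euclidean"))
  matrix(as.numeric(m), nrow(v), ncol(v))
}

#' Multi-scale peak detection on a distance map
#'
#' For each smoothing scale (finest first) the Gaussian-smoothed distance
#' map's local maxima are collected, subject to (i) a minimum peak spacing
#' of \code{minPeakDistanceFrac * expectedDiameterPx} — enforced greedily
#' in decreasing order of smoothed value, with earlier (finer) scales
#' taking precedence — and (ii) a floor on the raw distance value,
#' \code{floorFactor * expectedDiameterPx / 2}, that suppresses spurious
#' shallow maxima.
#'
#' @param dist numeric distance map.
#' @param config a \code{\link{postprocessConfig}}.
#' @param scales smoothing sigmas; defaults to \code{config$peakScales}.
#' @param floorFactor distance-value floor as a fraction of the expected
#'   radius, default 0.25.
#' @return data.frame with columns x, y (0-based) and value (raw distance
#'   at the peak); zero rows when no peaks.
#' @export
detectPeaks <- function(dist, config, scales = config$peakScales,
                        floorFactor = 0.25) {
  stopifnot(inherits(config, "PostprocessConfig"))
  dist <- as.matrix(dist)
  empty <- data.frame(x = numeric(), y = numeric(), value = numeric())
  if (all(dist <= 0)) return(empty)
  minDist <- max(1, config$minPeakDistanceFrac * config$expectedDiameterPx)
  floorVal <- floorFactor * config$expectedDiameterPx
  # suppression window at half the spacing so that peak pairs at exactly
  # the minimum spacing are not lost; the spacing itself is enforced
  # greedily below, up to the 1 px pixel-grid quantum
  rad <- max(1L, as.integer(floor(minDist / 2)))
  minDistEff <- max(1, minDist - 1)
  accX <- numeric(0); accY <- numeric(0); accV <- numeric(0)
  for (sg in sort(scales)) {
    sm <- gaussianSmooth(dist, sg)
    isMax <- sm >= maxFilter(sm, rad) & dist > floorVal
    idx <- which(isMax)
    if (!length(idx)) next
    rr <- (idx - 1L) %% nrow(dist) + 1L
    cc <- (idx - 1L) %/% nrow(dist) + 1L
    ord <- order(-sm[idx], rr, cc)
    for (k in ord) {
      x <- cc[k] - 1; y <- rr[k] - 1
      if (!length(accX) ||
          all((accX - x)^2 + (accY - y)^2 >= minDistEff^2)) {
        accX <- c(accX, x); accY <- c(accY, y)
        accV <- c(accV, dist[rr[k], cc[k]])
      }
    }
  }
  data.frame(x = accX, y = accY, value = accV)
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion;
# returns the outer contour arc length with diagonal steps weighted
# sqrt(2). Single-pixel regions are assigned the perimeter of the
# equivalent disk (circularity exactly 1).
tracePerimeter <- function(inRegion) {
  n <- sum(inRegion)
  if (n == 1L) return(2 * sqrt(pi))
  nr <- nrow(inRegion); nc <- ncol(inRegion)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc &&
    inRegion[r, c]
  # clockwise from North: N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  stepLen <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  dirIndex <- matrix(NA_integer_, 3, 3)
  for (d in 1:8) dirIndex[dr[d] + 2L, dc[d] + 2L] <- d
  start <- which(inRegion)[1]            # topmost pixel of leftmost column
  sr <- (start - 1L) %% nr + 1L
  sc <- (start - 1L) %/% nr + 1L
  # scan clockwise starting just after the backtrack; returns the move
  # direction and the absolute position of the last background examined
  nextMove <- function(cr, cc, b) {
    for (s in 1:8) {
      d <- (b + s - 1L) %% 8L + 1L
      if (at(cr + dr[d], cc + dc[d])) {
        pd <- if (s == 1L) b else (b + s - 2L) %% 8L + 1L
        return(c(d, cr + dr[pd], cc + dc[pd]))
      }
    }
    NULL
  }
  cr <- sr; cc <- sc
  b <- 7L                                 # West neighbour is background
  mv <- nextMove(cr, cc, b)
  if (is.null(mv)) return(2 * sqrt(pi * n))  # disconnected fallback
  d0 <- mv[1]
  perim <- 0
  steps <- 0L
  maxSteps <- 8L * n + 8L
  repeat {
    d <- mv[1]
    perim <- perim + stepLen[d]
    bpr <- mv[2]; bpc <- mv[3]
    cr <- cr + dr[d]; cc <- cc + dc[d]
    b <- dirIndex[bpr - cr + 2L, bpc - cc + 2L]
    steps <- steps + 1L
    if (steps > maxSteps) break
    mv <- nextMove(cr, cc, b)
    if (is.null(mv)) break
    if (cr == sr && cc == sc && mv[1] == d0) break
  }
  perim
}

# Per-region shape statistics for a label matrix.
computeRegionStats <- function(labels) {
  labs <- sort(unique(as.integer(labels[labels > 0])))
  nr <- nrow(labels); nc <- ncol(labels)
  if (!length(labs)) {
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), x = numeric(), y = numeric(),
                      equivDiameter = numeric(), circularity = numeric(),
                      touchesBorder = logical()))
  }
  out <- lapply(labs, function(k) {
    idx <- which(labels == k)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    sub <- matrix(FALSE, max(rr) - min(rr) + 1L, max(cc) - min(cc) + 1L)
    sub[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
    A <- length(idx)
    P <- tracePerimeter(sub)
    data.frame(label = k, area = A, perimeter = P,
               x = mean(cc - 1), y = mean(rr - 1),
               equivDiameter = 2 * sqrt(A / pi),
               circularity = min(1, 4 * pi * A / P^2),
               touchesBorder = any(rr == 1L | rr == nr | cc == 1L |
                                     cc == nc))
  })
  do.call(rbind, out)
}

#' Marker-controlled watershed splitting
#'
#' Floods the foreground from the seed markers in order of decreasing
#' distance-map value (the watershed of the negated distance map restricted
#' to the foreground): each unlabeled foreground pixel takes the label of
#' its highest neighbouring labelled pixel, so touching particles are split
#' along the distance-map saddle. Seeds falling on background are dropped
#' with a warning. Foreground components containing no seed stay
#' unlabeled.
#'
#' @param binary binary \linkS4class{SegmentationMask} or 0/1 matrix.
#' @param seeds data.frame with columns x, y (0-based), e.g. from
#'   \code{\link{detectPeaks}}.
#' @param dist distance map of \code{binary} (recomputed when missing).
#' @return A \linkS4class{LabeledRegions}.
#' @export
watershedSplit <- function(binary, seeds, dist = NULL) {
  v <- if (is(binary, "SegmentationMask")) binary@values
       else as.matrix(binary)
  if (is.null(dist)) dist <- distanceMap(v)
  nr <- nrow(v); nc <- ncol(v)
  labels <- matrix(0L, nr, nc)
  if (nrow(seeds)) {
    sr <- round(seeds$y) + 1L
    sc <- round(seeds$x) + 1L
    onFg <- sr >= 1L & sr <= nr & sc >= 1L & sc <= nc &
      v[cbind(pmin(pmax(sr, 1L), nr), pmin(pmax(sc, 1L), nc))] == 1
    if (any(!onFg))
      warning(sum(!onFg), " seed(s) on background dropped")
    sr <- sr[onFg]; sc <- sc[onFg]
    for (k in seq_along(sr)) labels[sr[k], sc[k]] <- k
  }
  if (any(labels > 0)) {
    fg <- which(v == 1 & labels == 0L)
    if (length(fg)) {
      ord <- fg[order(-dist[fg], fg)]
      rr <- (ord - 1L) %% nr + 1L
      cc <- (ord - 1L) %/% nr + 1L
      offR <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
      offC <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
      nbr <- matrix(NA_integer_, length(ord), 8L)
      for (q in 1:8) {
        r2 <- rr + offR[q]; c2 <- cc + offC[q]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        nbr[ok, q] <- (c2[ok] - 1L) * nr + r2[ok]
      }
      pending <- seq_along(ord)
      repeat {
        changed <- FALSE
        still <- integer(0)
        for (t in pending) {
          nIdx <- nbr[t, ]
          nIdx <- nIdx[!is.na(nIdx)]
          nLab <- labels[nIdx]
          lab <- nIdx[nLab > 0L]
          if (length(lab)) {
            best <- lab[which.max(dist[lab])]
            labels[ord[t]] <- labels[best]
            changed <- TRUE
          } else {
            still <- c(still, t)
          }
        }
        pending <- still
        if (!changed || !length(pending)) break
      }
    }
  }
  # compact labels (seeds may have been dropped or flooded regions merged)
  present <- sort(unique(as.integer(labels[labels > 0L])))
  if (length(present) && !identical(present, seq_along(present))) {
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  new("LabeledRegions", labels = labels,
      stats = computeRegionStats(labels))
}

#' Geometric plausibility filter
#'
#' Keeps regions whose area lies within \code{areaRange} multiples of the
#' expected disk area \code{pi * (expectedDiameterPx / 2)^2} and whose
#' circularity \code{4 * pi * A / P^2} (perimeter by contour arc length) is
#' at least \code{minCircularity}; optionally drops border-touching
#' regions. Labels are re-compacted.
#'
#' @param regions a \linkS4class{LabeledRegions}.
#' @param config a \code{\link{postprocessConfig}}.
#' @return A filtered \linkS4class{LabeledRegions}.
#' @export
geometricFilter <- function(regions, config) {
  stopifnot(is(regions, "LabeledRegions"),
            inherits(config, "PostprocessConfig"))
  st <- regions@stats
  if (!nrow(st)) return(regions)
  diskArea <- pi * (config$expectedDiameterPx / 2)^2
  keep <- st$area >= config$areaRange[1] * diskArea &
    st$area <= config$areaRange[2] * diskArea &
    st$circularity >= config$minCircularity
  if (config$dropBorder) keep <- keep & !st$touchesBorder
  labels <- regions@labels
  labels[!(labels %in% st$label[keep])] <- 0L
  st <- st[keep, , drop = FALSE]
  if (nrow(st)) {
    remap <- integer(max(st$label))
    remap[st$label] <- seq_len(nrow(st))
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    st$label <- seq_len(nrow(st))
    rownames(st) <- NULL
  }
  new("LabeledRegions", labels = labels, stats = st)
}

# Shared core of the localization passes. Returns per-particle rows plus
# the pixel indices of each accepted region (for erasure and scoring).
localizeOnce <- function(v, dist, config, scales, floorFactor) {
  seeds <- detectPeaks(dist, config, scales = scales,
                       floorFactor = floorFactor)
  if (!nrow(seeds))
    return(list(stats = NULL, pixels = list()))
  ws <- suppressWarnings(watershedSplit(v, seeds, dist))
  gf <- geometricFilter(ws, config)
  st <- gf@stats
  if (!nrow(st)) return(list(stats = NULL, pixels = list()))
  pix <- lapply(st$label, function(k) which(gf@labels == k))
  # tie-break value: raw distance at the region's internal maximum
  st$distVal <- vapply(pix, function(ix) max(dist[ix]), 0)
  list(stats = st, pixels = pix)
}

#' Dual-pass particle localization
#'
#' Pass 1: multi-scale peaks, watershed, geometric filter. Pass 2 (when
#' \code{dualPass}): the accepted regions are erased from the mask, the
#' distance map is recomputed on the residual foreground, and peak
#' detection is re-run with the finest scale only and a halved
#' distance-value floor, recovering closely packed particles suppressed by
#' their neighbours in pass 1. Finally, deduplication removes any center
#' within \code{minSeparationFrac * expectedDiameterPx} of an
#' earlier-accepted center; pass-1 centers have priority, then higher
#' distance-map value, then (y, x) order.
#'
#' @param binary binary \linkS4class{SegmentationMask} or 0/1 matrix.
#' @param dist its distance map (recomputed when missing).
#' @param config a \code{\link{postprocessConfig}}.
#' @return A predicted \linkS4class{ParticleSet} (diameter = region
#'   equivalent diameter).
#' @export
dualPassLocalize <- function(binary, dist = NULL, config) {
  res <- localizeParticlesInternal(binary, dist, config, prob = NULL)
  res$particles
}

localizeParticlesInternal <- function(binary, dist = NULL, config,
                                      prob = NULL) {
  stopifnot(inherits(config, "PostprocessConfig"))
  v <- if (is(binary, "SegmentationMask")) binary@values
       else as.matrix(binary)
  if (is.null(dist)) dist <- distanceMap(v)
  shape <- dim(v)
  p1 <- localizeOnce(v, dist, config, config$peakScales, 0.25)
  rows <- list(); pixes <- list()
  if (!is.null(p1$stats)) {
    s <- p1$stats; s$pass <- 1L
    rows[[1]] <- s
    pixes <- p1$pixels
  }
  if (config$dualPass) {
    v2 <- v
    for (ix in pixes) v2[ix] <- 0
    if (any(v2 == 1)) {
      dist2 <- distanceMap(v2)
      p2 <- localizeOnce(v2, dist2, config, min(config$peakScales), 0.125)
      if (!is.null(p2$stats)) {
        s <- p2$stats; s$pass <- 2L
        rows[[length(rows) + 1L]] <- s
        pixes <- c(pixes, p2$pixels)
      }
    }
  }
  if (!length(rows)) {
    return(list(particles = ParticleSet(referenceShape = shape,
                                        provenance = "predicted"),
                pixels = list()))
  }
  all <- do.call(rbind, rows)
  ord <- order(all$pass, -all$distVal, all$y, all$x)
  all <- all[ord, , drop = FALSE]
  pixes <- pixes[ord]
  minSep <- config$minSeparationFrac * config$expectedDiameterPx
  keep <- logical(nrow(all))
  for (k in seq_len(nrow(all))) {
    prev <- which(keep)
    keep[k] <- !length(prev) ||
      all((all$x[prev] - all$x[k])^2 + (all$y[prev] - all$y[k])^2 >=
            minSep^2)
  }
  all <- all[keep, , drop = FALSE]
  pixes <- pixes[keep]
  score <- if (!is.null(prob)) {
    vapply(pixes, function(ix) min(max(mean(prob[ix]), 0), 1), 0)
  } else NA_real_
  ps <- ParticleSet(x = all$x, y = all$y, diameter = all$equivDiameter,
                    score = score, referenceShape = shape,
                    provenance = "predicted")
  list(particles = ps, pixels = pixes)
}

#' Convert a probability mask to particle coordinates
#'
#' Composition of \code{\link{binarizeMask}}, \code{\link{distanceMap}} and
#' \code{\link{dualPassLocalize}}. Each particle's diameter is its region's
#' equivalent diameter and its score the mean mask probability over the
#' region (clipped to [0, 1]).
#'
#' @param mask probability (or binary) \linkS4class{SegmentationMask}.
#' @param config a \code{\link{postprocessConfig}}.
#' @return A predicted \linkS4class{ParticleSet}.
#' @examples
#' out <- simulateMicrograph(syntheticSpec(nParticles = 4, seed = 2))
#' cfg <- postprocessConfig(expectedDiameterPx = 16)
#' masksToParticles(out$mask, cfg)
#' @export
masksToParticles <- function(mask, config) {
  stopifnot(inherits(config, "PostprocessConfig"))
  v <- if (is(mask, "SegmentationMask")) mask@values else as.matrix(mask)
  bin <- binarizeMask(v, config$threshold)
  res <- localizeParticlesInternal(bin, NULL, config, prob = v)
  res$particles
}
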