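# Particle matching and picking metrics: greedy nearest-first one-to-one
# matching within a radius, precision/recall/F1 on the matched counts, and
# IoU on rasterized disk unions.

#' Match predicted particles to ground truth
#'
#' One-to-one matching within a radius: all predicted/ground-truth pairs
#' within \code{matchRadius} are first paired greedily by ascending center
#' distance (ties by predicted then ground-truth index); the pairing is
#' then completed with augmenting paths, so the returned matching always
#' has maximum cardinality among radius-feasible one-to-one pairings while
#' preferring nearest pairs. TP = accepted pairs, FP = unmatched
#' predictions, FN = unmatched ground truth.
#'
#' @param pred,gt \linkS4class{ParticleSet}s sharing a reference shape.
#' @param matchRadius maximum pairing distance in pixels (> 0); a common
#'   choice is half the expected particle diameter.
#' @return A \linkS4class{MatchResult}.
#' @examples
#' gt <- ParticleSet(x = c(10, 30), y = c(10, 30), diameter = 8,
#'                   referenceShape = c(64, 64), provenance = "ground_truth")
#' matchCounts(matchParticles(gt, gt, matchRadius = 4))
#' @export
matchParticles <- function(pred, gt, matchRadius) {
  stopifnot(is(pred, "ParticleSet"), is(gt, "ParticleSet"))
  if (!is.finite(matchRadius) || matchRadius <= 0)
    stop("matchRadius must be > 0", call. = FALSE)
  p <- pred@coords; g <- gt@coords
  nP <- nrow(p); nG <- nrow(g)
  pairs <- data.frame(predIndex = integer(), gtIndex = integer(),
                      distance = numeric())
  if (nP && nG) {
    dmat <- outer(p$x, g$x, "-")^2 + outer(p$y, g$y, "-")^2
    cand <- which(dmat <= matchRadius^2, arr.ind = TRUE)
    if (nrow(cand)) {
      dd <- sqrt(dmat[cand])
      ord <- order(dd, cand[, 1], cand[, 2])
      matchOfG <- integer(nG)   # pred index matched to each gt (0 = free)
      matchOfP <- integer(nP)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!matchOfP[i] && !matchOfG[j]) {
          matchOfP[i] <- j; matchOfG[j] <- i
        }
      }
      # complete to maximum cardinality with augmenting paths; nearest
      # candidates are tried first so pairings stay short
      adj <- split(cand[ord, 2], cand[ord, 1])
      visited <- logical(nG)
      augment <- function(i) {
        for (j in adj[[as.character(i)]]) {
          if (!visited[j]) {
            visited[j] <<- TRUE
            if (!matchOfG[j] || augment(matchOfG[j])) {
              matchOfP[i] <<- j; matchOfG[j] <<- i
              return(TRUE)
            }
          }
        }
        FALSE
      }
      for (i in seq_len(nP)) {
        if (!matchOfP[i] && !is.null(adj[[as.character(i)]])) {
          visited[] <- FALSE
          augment(i)
        }
      }
      keepP <- which(matchOfP > 0L)
      keepG <- matchOfP[keepP]
      pairs <- data.frame(predIndex = keepP, gtIndex = keepG,
                          distance = sqrt(dmat[cbind(keepP, keepG)]))
    }
  }
  tp <- nrow(pairs)
  new("MatchResult", tp = as.integer(tp), fp = as.integer(nP - tp),
      fn = as.integer(nG - tp), pairs = pairs,
      matchRadius = as.numeric(matchRadius))
}

#' Precision, recall and F1 from a match result
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)},
#' \code{f1 = 2 P R / (P + R)}; all 0/0 cases resolve to 0 by convention.
#'
#' @param m a \linkS4class{MatchResult} (or list with tp/fp/fn).
#' @return named numeric c(precision, recall, f1).
#' @export
precisionRecallF1 <- function(m) {
  if (is(m, "MatchResult")) {
    tp <- m@tp; fp <- m@fp; fn <- m@fn
  } else {
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

# Rasterize a particle set as the union of its disks (logical matrix).
rasterizeParticles <- function(ps, shape = NULL) {
  if (is.null(shape)) shape <- ps@referenceShape
  if (any(is.na(shape)))
    stop("particle set needs a reference shape for rasterization",
         call. = FALSE)
  out <- matrix(FALSE, shape[1], shape[2])
  cc <- ps@coords
  if (any(is.na(cc$diameter)))
    stop("all particles need diameters for rasterization", call. = FALSE)
  for (k in seq_len(nrow(cc))) {
    dd <- renderDisk(shape, cc$x[k], cc$y[k], cc$diameter[k])
    out[dd$rows, dd$cols] <- out[dd$rows, dd$cols] | dd$hard
  }
  out
}

#' Intersection-over-union of two particle sets
#'
#' Both sets are rasterized as unions of their particle disks on the shared
#' reference grid; the IoU is the pixel-count ratio
#' \code{|intersection| / |union|} (0 when the union is empty). Symmetric
#' in its arguments.
#'
#' @param pred,gt \linkS4class{ParticleSet}s with diameters and a shared
#'   reference shape.
#' @return numeric in [0, 1].
#' @export
particleIoU <- function(pred, gt) {
  stopifnot(is(pred, "ParticleSet"), is(gt, "ParticleSet"))
  shape <- pred@referenceShape
  if (any(is.na(shape))) shape <- gt@referenceShape
  a <- rasterizeParticles(pred, shape)
  b <- rasterizeParticles(gt, shape)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Per-micrograph picking metrics for a method
#'
#' Convenience wrapper producing one row of a metric table: matches
#' \code{pred} against \code{gt} at \code{matchRadius} and reports
#' precision, recall, F1 and disk IoU.
#'
#' @param pred,gt \linkS4class{ParticleSet}s.
#' @param matchRadius pairing radius in pixels.
#' @return data.frame with columns precision, recall, f1, iou.
#' @export
evaluatePicking <- function(pred, gt, matchRadius) {
  m <- matchParticles(pred, gt, matchRadius)
  prf <- precisionRecallF1(m)
  iou <- tryCatch(particleIoU(pred, gt), error = function(e) NA_real_)
  data.frame(precision = prf["precision"], recall = prf["recall"],
             f1 = prf["f1"], iou = iou, row.names = NULL)
}
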