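# Surrogate hierarchical encoder: a small frozen tower honoring the
# four-stage contract of hierarchical vision transformers (per-stage
# embedding width, per-stage block list, 2x spatial reduction between
# stages, block inputs exposed for pre-block residual modulation). Blocks
# are residual token MLPs; the patch embedding is a frozen linear map of
# non-overlapping patches. Feature maps are stored in token form: an
# N x D matrix whose row t is the spatial position (r, c) with
# t = (c - 1) * H + r (column-major), matching R's matrix vectorization.

#' Build a frozen surrogate hierarchical encoder
#'
#' @param stageDims per-stage embedding widths.
#' @param stageDepths per-stage block counts.
#' @param patchStride patch embedding stride (stage-1 spatial reduction).
#' @param seed integer seed; identical seeds give identical encoders.
#' @param frozen logical; frozen encoders are never updated by training.
#' @return An object of class \code{"SurrogateEncoder"}.
#' @examples
#' enc <- buildSurrogateEncoder(c(8, 16, 32, 64), c(1, 1, 2, 1),
#'                              patchStride = 4)
#' encoderStageShapes(enc, c(64, 64))
#' @export
buildSurrogateEncoder <- function(stageDims = c(16L, 32L, 64L, 128L),
                                  stageDepths = c(2L, 2L, 2L, 2L),
                                  patchStride = 2L, seed = 1L,
                                  frozen = TRUE) {
  stageDims <- as.integer(stageDims)
  stageDepths <- as.integer(stageDepths)
  if (length(stageDims) != length(stageDepths))
    stop("stageDims and stageDepths must have equal length", call. = FALSE)
  if (any(stageDims <= 0L) || any(stageDepths <= 0L))
    stop("stage dims and depths must be positive", call. = FALSE)
  p <- as.integer(patchStride)
  if (p < 1L) stop("patchStride must be >= 1", call. = FALSE)
  nS <- length(stageDims)
  params <- withSeed(seed, {
    lin <- function(nin, nout, scale = 1)
      list(W = matrix(rnorm(nin * nout, sd = scale / sqrt(nin)), nin, nout),
           b = numeric(nout))
    list(
      patch = lin(p * p, stageDims[1]),
      stages = lapply(seq_len(nS), function(i) {
        lapply(seq_len(stageDepths[i]), function(j) {
          list(W1 = matrix(rnorm(stageDims[i]^2, sd = 1 / sqrt(stageDims[i])),
                           stageDims[i], stageDims[i]),
               b1 = numeric(stageDims[i]),
               W2 = matrix(rnorm(stageDims[i]^2,
                                 sd = 0.5 / sqrt(stageDims[i])),
                           stageDims[i], stageDims[i]),
               b2 = numeric(stageDims[i]))
        })
      }),
      down = lapply(seq_len(max(nS - 1L, 0L)), function(i) {
        lin(stageDims[i], stageDims[i + 1])
      }))
  })
  structure(list(stageDims = stageDims, stageDepths = stageDepths,
                 patchStride = p, seed = as.integer(seed),
                 frozen = isTRUE(frozen), params = params),
            class = "SurrogateEncoder")
}

#' @export
print.SurrogateEncoder <- function(x, ...) {
  cat(sprintf(
    "SurrogateEncoder: %d stage(s), dims [%s], depths [%s], stride %d%s\n",
    length(x$stageDims), paste(x$stageDims, collapse = ", "),
    paste(x$stageDepths, collapse = ", "), x$patchStride,
    if (x$frozen) " (frozen)" else ""))
  invisible(x)
}

#' Per-stage spatial shapes for a given input shape
#'
#' Stage i has shape \code{inputShape / (patchStride * 2^(i-1))}; the input
#' must be an exact multiple of the total stride.
#'
#' @param encoder a \code{"SurrogateEncoder"}.
#' @param inputShape integer(2) image shape (height, width).
#' @return list of integer(2) per-stage shapes.
#' @export
encoderStageShapes <- function(encoder, inputShape) {
  nS <- length(encoder$stageDims)
  total <- encoder$patchStride * 2^(nS - 1L)
  if (any(inputShape %% total != 0))
    contractError("input shape (", inputShape[1], ", ", inputShape[2],
                  ") is not a multiple of the encoder stride ", total)
  lapply(seq_len(nS), function(i) {
    as.integer(inputShape / (encoder$patchStride * 2^(i - 1L)))
  })
}

# Extract non-overlapping p x p patches as an N x p^2 matrix in token order.
patchify <- function(img, p) {
  H1 <- nrow(img) %/% p
  W1 <- ncol(img) %/% p
  a <- array(img, dim = c(p, H1, p, W1))
  a <- aperm(a, c(2, 4, 1, 3))           # (r1, c1, dr, dc)
  matrix(a, H1 * W1, p * p)
}

# 2x2 mean-pool index quadruples for an H x W token grid (column-major).
poolIndices <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), W2)
  c2 <- rep(seq_len(W2), each = H2)
  idx <- function(r, c) (c - 1L) * H + r
  cbind(idx(2L * r2 - 1L, 2L * c2 - 1L), idx(2L * r2, 2L * c2 - 1L),
        idx(2L * r2 - 1L, 2L * c2), idx(2L * r2, 2L * c2))
}

# Nearest upsample map: token index in the (H, W) grid for each token of
# the (H * f, W * f) grid.
upsampleIndex <- function(H, W, f) {
  Hf <- H * f; Wf <- W * f
  r <- rep(seq_len(Hf), Wf)
  c <- rep(seq_len(Wf), each = Hf)
  ((c - 1L) %/% f) * H + ((r - 1L) %/% f) + 1L
}

# Full encoder (+ optional adapter) forward pass.
# Returns stage outputs (token matrices after each stage's blocks, before
# downsampling) and, when keepCache, every intermediate needed by
# encoderBackward.
encoderForward <- function(encoder, image, adapters = NULL,
                           fftStreams = NULL, keepCache = FALSE) {
  stopifnot(inherits(encoder, "SurrogateEncoder"))
  img <- if (is(image, "Micrograph")) image@pixels else as.matrix(image)
  shapes <- encoderStageShapes(encoder, dim(img))
  nS <- length(encoder$stageDims)
  if (!is.null(adapters)) {
    if (!identical(as.integer(adapters$config$stageDims),
                   encoder$stageDims))
      contractError("adapter stage dims [",
                    paste(adapters$config$stageDims, collapse = ", "),
                    "] do not match encoder stage dims [",
                    paste(encoder$stageDims, collapse = ", "), "]")
    if (is.null(fftStreams))
      fftStreams <- prepareFFTStream(img, shapes,
                                     adapters$config$fftCutoffFraction)
    fftVecs <- lapply(fftStreams, as.vector)
  } else {
    fftVecs <- vector("list", nS)
  }
  P <- encoder$params
  X <- patchify(img, encoder$patchStride)
  feat <- sweep(X %*% P$patch$W, 2, P$patch$b, "+")
  stageOutputs <- vector("list", nS)
  cache <- if (keepCache) {
    list(shapes = shapes, fftVecs = fftVecs, stages = vector("list", nS),
         pool = vector("list", nS), poolIn = vector("list", nS))
  } else NULL
  for (i in seq_len(nS)) {
    blocksCache <- if (keepCache)
      vector("list", encoder$stageDepths[i]) else NULL
    for (j in seq_len(encoder$stageDepths[i])) {
      featIn <- feat
      if (!is.null(adapters)) {
        st <- adapters$stages[[i]]
        bl <- st$blocks[[j]]
        u <- featIn %*% st$E + outer(fftVecs[[i]], st$wF)
        u <- sweep(u, 2, st$bE + st$bF, "+")
        v <- sweep(u %*% bl$U, 2, bl$bU, "+")
        g <- gelu(v)
        featMid <- featIn + sweep(g %*% st$S, 2, st$bS, "+")
      } else {
        u <- v <- g <- NULL
        featMid <- featIn
      }
      B <- P$stages[[i]][[j]]
      a1 <- sweep(featMid %*% B$W1, 2, B$b1, "+")
      h <- gelu(a1)
      feat <- featMid + sweep(h %*% B$W2, 2, B$b2, "+")
      if (keepCache)
        blocksCache[[j]] <- list(featIn = featIn, u = u, v = v, g = g,
                                 a1 = a1, h = h)
    }
    stageOutputs[[i]] <- feat
    if (keepCache) cache$stages[[i]] <- blocksCache
    if (i < nS) {
      pidx <- poolIndices(shapes[[i]][1], shapes[[i]][2])
      pooled <- (feat[pidx[, 1], , drop = FALSE] +
                 feat[pidx[, 2], , drop = FALSE] +
                 feat[pidx[, 3], , drop = FALSE] +
                 feat[pidx[, 4], , drop = FALSE]) / 4
      if (keepCache) {
        cache$pool[[i]] <- pidx
        cache$poolIn[[i]] <- pooled
      }
      feat <- sweep(pooled %*% P$down[[i]]$W, 2, P$down[[i]]$b, "+")
    }
  }
  list(stageOutputs = stageOutputs, final = stageOutputs[[nS]],
       shapes = shapes, cache = cache)
}

# Backpropagate gradients w.r.t. each stage output through the (frozen)
# encoder, accumulating gradients of the adapter parameters only.
# dStageOutputs: list of N_i x D_i gradient matrices (NULL entries allowed).
# Returns list(adapterGrads) with the AdapterParams$stages structure.
encoderBackward <- function(encoder, adapters, cache, dStageOutputs) {
  P <- encoder$params
  nS <- length(encoder$stageDims)
  aGrads <- if (!is.null(adapters)) zeroLike(adapters$stages) else NULL
  dfeat <- NULL
  for (i in rev(seq_len(nS))) {
    dOut <- dStageOutputs[[i]]
    if (i < nS) {
      # back through downsample linear + 2x2 mean pool into stage i output
      dPooled <- dfeat %*% t(P$down[[i]]$W)
      pidx <- cache$pool[[i]]
      dUnpooled <- matrix(0, nrow(cache$stages[[i]][[1]]$featIn),
                          encoder$stageDims[i])
      for (q in 1:4) {
        dUnpooled[pidx[, q], ] <- dUnpooled[pidx[, q], ] + dPooled / 4
      }
      dOut <- if (is.null(dOut)) dUnpooled else dOut + dUnpooled
    }
    if (is.null(dOut))
      dOut <- matrix(0, nrow(cache$stages[[i]][[1]]$featIn),
                     encoder$stageDims[i])
    dfeat <- dOut
    for (j in rev(seq_len(encoder$stageDepths[i]))) {
      cb <- cache$stages[[i]][[j]]
      B <- P$stages[[i]][[j]]
      # block: feat = featMid + gelu(featMid W1 + b1) W2 + b2
      dA1 <- (dfeat %*% t(B$W2)) * geluGrad(cb$a1)
      dMid <- dfeat + dA1 %*% t(B$W1)
      if (!is.null(adapters)) {
        st <- adapters$stages[[i]]
        bl <- st$blocks[[j]]
        dr <- dMid
        aGrads[[i]]$S <- aGrads[[i]]$S + t(cb$g) %*% dr
        aGrads[[i]]$bS <- aGrads[[i]]$bS + colSums(dr)
        dg <- dr %*% t(st$S)
        dv <- dg * geluGrad(cb$v)
        aGrads[[i]]$blocks[[j]]$U <- aGrads[[i]]$blocks[[j]]$U +
          t(cb$u) %*% dv
        aGrads[[i]]$blocks[[j]]$bU <- aGrads[[i]]$blocks[[j]]$bU +
          colSums(dv)
        du <- dv %*% t(bl$U)
        aGrads[[i]]$E <- aGrads[[i]]$E + t(cb$featIn) %*% du
        aGrads[[i]]$bE <- aGrads[[i]]$bE + colSums(du)
        aGrads[[i]]$wF <- aGrads[[i]]$wF +
          as.vector(crossprod(cache$fftVecs[[i]], du))
        aGrads[[i]]$bF <- aGrads[[i]]$bF + colSums(du)
        dfeat <- dMid + du %*% t(st$E)
      } else {
        dfeat <- dMid
      }
    }
  }
  list(adapterGrads = aGrads)
}

#' Attach an adapter stack to a frozen encoder
#'
#' Bundles encoder and adapters into an adapted encoder whose forward pass
#' applies each adapter to the corresponding block input before the block
#' runs. The encoder parameters are shared, never copied or modified;
#' \code{detachAdapters} returns the original encoder, whose output is
#' therefore restored exactly.
#'
#' @param encoder a \code{"SurrogateEncoder"}.
#' @param adapters an \code{"AdapterParams"} whose config matches the
#'   encoder's stage dims.
#' @return An object of class \code{"AdaptedEncoder"}.
#' @export
attachAdapters <- function(encoder, adapters) {
  stopifnot(inherits(encoder, "SurrogateEncoder"),
            inherits(adapters, "AdapterParams"))
  if (!identical(as.integer(adapters$config$stageDims), encoder$stageDims))
    contractError("adapter stage dims [",
                  paste(adapters$config$stageDims, collapse = ", "),
                  "] do not match encoder stage dims [",
                  paste(encoder$stageDims, collapse = ", "), "]")
  structure(list(encoder = encoder, adapters = adapters),
            class = "AdaptedEncoder")
}

#' @rdname attachAdapters
#' @param adapted an \code{"AdaptedEncoder"}.
#' @export
detachAdapters <- function(adapted) {
  stopifnot(inherits(adapted, "AdaptedEncoder"))
  adapted$encoder
}

#' Forward features through a (possibly adapted) encoder
#'
#' @param x a \code{"SurrogateEncoder"} or \code{"AdaptedEncoder"}.
#' @param image a \linkS4class{Micrograph} or numeric matrix whose shape is
#'   a multiple of the encoder stride.
#' @return list with \code{stageOutputs} (token matrices), \code{final} and
#'   \code{shapes}.
#' @export
forwardFeatures <- function(x, image) {
  if (inherits(x, "AdaptedEncoder")) {
    out <- encoderForward(x$encoder, image, adapters = x$adapters)
  } else {
    out <- encoderForward(x, image)
  }
  out[c("stageOutputs", "final", "shapes")]
}
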