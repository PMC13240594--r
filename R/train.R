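# Few-shot segmentation training: the encoder stays frozen; only the
# adapter stack and a small decoder head are updated (Adam, balanced
# BCE-with-logits, batch size 2 by default). The decoder head fuses all
# stage outputs at stage-1 resolution — upsampled and linearly projected —
# mirroring how full-scale mask decoders consume high-resolution skip
# features from the early hierarchical stages, then maps the fused map to
# full-resolution logits by bilinear interpolation.

#' Training configuration
#'
#' @param inputSize square working resolution; micrographs are bilinearly
#'   resized to \code{inputSize x inputSize} (masks: nearest) before
#'   encoding. Default 1024 for full-scale encoders; desk-scale surrogate
#'   runs use 128–256.
#' @param batchSize images per optimizer step (default 2).
#' @param learningRate Adam learning rate (default 1e-4).
#' @param maxEpochs epoch cap (default 4000; desk-scale runs use <= 300).
#' @param seed RNG seed controlling initialization and batch order.
#' @param posWeightMode "auto" (per-batch background/foreground ratio,
#'   clipped to [1, 100]) or "fixed".
#' @param posWeight positive-class weight used when
#'   \code{posWeightMode = "fixed"}.
#' @param threshold binarization threshold for predicted masks.
#' @param headChannels width of the decoder head's fused feature map.
#' @return A validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(inputSize = 1024L, batchSize = 2L,
                        learningRate = 1e-4, maxEpochs = 4000L, seed = 1L,
                        posWeightMode = c("auto", "fixed"), posWeight = 1,
                        threshold = 0.5, headChannels = 16L) {
  posWeightMode <- match.arg(posWeightMode)
  cfg <- list(inputSize = as.integer(inputSize),
              batchSize = as.integer(batchSize),
              learningRate = as.numeric(learningRate),
              maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
              posWeightMode = posWeightMode,
              posWeight = as.numeric(posWeight),
              threshold = as.numeric(threshold),
              headChannels = as.integer(headChannels))
  if (cfg$batchSize < 1L) stop("batchSize must be >= 1", call. = FALSE)
  if (cfg$learningRate < 0) stop("learningRate must be >= 0", call. = FALSE)
  if (cfg$maxEpochs < 1L) stop("maxEpochs must be >= 1", call. = FALSE)
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "TrainConfig"
  cfg
}

#' Build a decoder head for a surrogate encoder
#'
#' Per stage: a linear projection of the (nearest-upsampled) stage output
#' to \code{channels} fused features at stage-1 resolution; a GELU; then a
#' zero-initialized linear map to one logit channel, bilinearly upsampled
#' to the working resolution. Zero initialization of the final layer makes
#' an untrained model output a uniform probability of 0.5.
#'
#' @param stageDims encoder stage widths.
#' @param channels fused feature width.
#' @param seed initialization seed.
#' @return An object of class \code{"DecoderHead"}.
#' @export
buildDecoderHead <- function(stageDims, channels = 16L, seed = 1L) {
  stageDims <- as.integer(stageDims)
  channels <- as.integer(channels)
  params <- withSeed(seed, {
    list(proj = lapply(stageDims, function(D) {
           matrix(rnorm(D * channels, sd = 1 / sqrt(D)), D, channels)
         }),
         bz = numeric(channels),
         ho = matrix(0, channels, 1),
         bo = 0)
  })
  structure(list(params = params, channels = channels,
                 stageDims = stageDims), class = "DecoderHead")
}

#' @export
print.DecoderHead <- function(x, ...) {
  cat(sprintf("DecoderHead: %d stage projections -> %d channels -> logits\n",
              length(x$params$proj), x$channels))
  invisible(x)
}

headForward <- function(head, stageOutputs, shapes, outShape,
                        keepCache = FALSE) {
  H1 <- shapes[[1]][1]; W1 <- shapes[[1]][2]
  nS <- length(stageOutputs)
  P <- head$params
  z <- matrix(0, H1 * W1, head$channels)
  upIdx <- vector("list", nS)
  ups <- vector("list", nS)
  for (i in seq_len(nS)) {
    f <- H1 %/% shapes[[i]][1]
    upIdx[[i]] <- if (f > 1L)
      upsampleIndex(shapes[[i]][1], shapes[[i]][2], f)
      else seq_len(nrow(stageOutputs[[i]]))
    ups[[i]] <- stageOutputs[[i]][upIdx[[i]], , drop = FALSE]
    z <- z + ups[[i]] %*% P$proj[[i]]
  }
  z <- sweep(z, 2, P$bz, "+")
  tz <- gelu(z)
  lc <- as.vector(tz %*% P$ho) + P$bo
  Lc <- matrix(lc, H1, W1)
  Br <- bilinearMatrix(outShape[1], H1)
  Bc <- bilinearMatrix(outShape[2], W1)
  logits <- Br %*% Lc %*% t(Bc)
  cache <- if (keepCache)
    list(z = z, tz = tz, ups = ups, upIdx = upIdx, Br = Br, Bc = Bc,
         H1 = H1, W1 = W1) else NULL
  list(logits = logits, cache = cache)
}

# Backward through the head. G: gradient w.r.t. full-resolution logits.
# Returns head parameter grads and per-stage gradients w.r.t. stage outputs.
headBackward <- function(head, cache, G, nTokensPerStage) {
  P <- head$params
  dLc <- t(cache$Br) %*% G %*% cache$Bc
  dlc <- as.vector(dLc)
  gr <- list(proj = vector("list", length(P$proj)),
             bz = numeric(length(P$bz)),
             ho = crossprod(cache$tz, dlc),
             bo = sum(dlc))
  dtz <- dlc %*% t(P$ho)
  dz <- dtz * geluGrad(cache$z)
  gr$bz <- colSums(dz)
  dStage <- vector("list", length(P$proj))
  for (i in seq_along(P$proj)) {
    gr$proj[[i]] <- crossprod(cache$ups[[i]], dz)
    dUp <- dz %*% t(P$proj[[i]])
    ds <- rowsum(dUp, cache$upIdx[[i]])        # groups 1..N_i, sorted
    dStage[[i]] <- matrix(0, nTokensPerStage[i], ncol(dUp))
    dStage[[i]][as.integer(rownames(ds)), ] <- ds
  }
  list(grads = gr, dStageOutputs = dStage)
}

#' Balanced binary cross-entropy with logits
#'
#' Mean over pixels of \code{-[posWeight * t * log(sigmoid(z)) + (1 - t) *
#' log(1 - sigmoid(z))]}, evaluated in a numerically stable softplus form.
#'
#' @param logits numeric array of logits.
#' @param target binary array of the same shape.
#' @param posWeight positive-class weight (>= 0).
#' @return scalar loss.
#' @examples
#' balancedBCE(matrix(0, 2, 2), matrix(c(1, 0, 0, 0), 2, 2), posWeight = 3)
#' # = mean(3*log(2), log(2), log(2), log(2)) = 1.5 * log(2)
#' @export
balancedBCE <- function(logits, target, posWeight = 1) {
  if (!identical(dim(logits), dim(target)))
    stop("logits and target must have the same shape", call. = FALSE)
  if (!all(target %in% c(0, 1)))
    stop("target must be binary", call. = FALSE)
  sp <- softplus(-logits)
  mean(posWeight * target * sp + (1 - target) * (logits + sp))
}

# d(loss)/d(logits) for the mean-reduced balanced BCE
balancedBCEGrad <- function(logits, target, posWeight = 1) {
  s <- sigmoid(logits)
  ((1 - target) * s - posWeight * target * (1 - s)) / length(logits)
}

# Per-batch automatic positive-class weight: background/foreground pixel
# ratio clipped to [1, 100]; degenerate all-fg/all-bg batches fall back to
# 1 with a warning.
autoPosWeight <- function(targets) {
  fg <- sum(vapply(targets, sum, 0))
  tot <- sum(vapply(targets, length, 0))
  bg <- tot - fg
  if (fg == 0 || bg == 0) {
    warning("degenerate batch (all foreground or all background); ",
            "posWeight falls back to 1")
    return(1)
  }
  min(max(bg / fg, 1), 100)
}

#' Train adapters and decoder head on a few-shot dataset
#'
#' The encoder is frozen: its parameters are shared by reference and never
#' written; training updates only the adapter stack and the decoder head.
#' Images are standardized (zero mean, unit variance) after resizing to the
#' working resolution; per-image FFT streams are precomputed once. The
#' per-epoch mean loss is recorded. Deterministic for a fixed seed and
#' platform.
#'
#' @param dataset a \linkS4class{FewShotDataset} with binary masks.
#' @param encoder a frozen \code{"SurrogateEncoder"}.
#' @param adapters an \code{"AdapterParams"} matching the encoder (built
#'   with \code{\link{buildAdapterStack}} when omitted, reduction 4).
#' @param head a \code{"DecoderHead"} (built automatically when omitted).
#' @param config a \code{\link{trainConfig}}.
#' @return An object of class \code{"cryofslModel"} with elements
#'   \code{encoder}, \code{adapters}, \code{head}, \code{config},
#'   \code{lossHistory}.
#' @export
trainFewShot <- function(dataset, encoder, adapters = NULL, head = NULL,
                         config = trainConfig()) {
  stopifnot(is(dataset, "FewShotDataset"),
            inherits(encoder, "SurrogateEncoder"),
            inherits(config, "TrainConfig"))
  if (dataset@K < 1L) stop("dataset is empty", call. = FALSE)
  for (it in dataset@items)
    if (!all(it$mask@values %in% c(0, 1)))
      stop("training masks must be binary", call. = FALSE)
  if (is.null(adapters)) {
    adapters <- buildAdapterStack(adapterStackConfig(
      stageDims = encoder$stageDims, stageDepths = encoder$stageDepths,
      reduction = 4L, seed = config$seed))
  }
  if (is.null(head))
    head <- buildDecoderHead(encoder$stageDims,
                             channels = config$headChannels,
                             seed = config$seed)
  sz <- c(config$inputSize, config$inputSize)
  shapes <- encoderStageShapes(encoder, sz)
  imgs <- lapply(dataset@items, function(it)
    standardizeMatrix(resizeBilinear(it$micrograph@pixels, sz)))
  msks <- lapply(dataset@items, function(it)
    resizeNearest(it$mask@values, sz))
  streams <- lapply(imgs, function(im)
    prepareFFTStream(im, shapes, adapters$config$fftCutoffFraction))
  nTok <- vapply(shapes, prod, 0)

  params <- list(A = adapters$stages, H = head$params)
  state <- adamInit(params)
  lossHistory <- numeric(0)
  K <- dataset@K
  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(K)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      epochLoss <- 0
      for (bt in batches) {
        pw <- if (config$posWeightMode == "auto")
          autoPosWeight(msks[bt]) else config$posWeight
        grads <- zeroLike(params)
        batchLoss <- 0
        for (ix in bt) {
          adapters$stages <- params$A
          head$params <- params$H
          fw <- encoderForward(encoder, imgs[[ix]], adapters = adapters,
                               fftStreams = streams[[ix]],
                               keepCache = TRUE)
          hf <- headForward(head, fw$stageOutputs, shapes, sz,
                            keepCache = TRUE)
          batchLoss <- batchLoss +
            balancedBCE(hf$logits, msks[[ix]], pw)
          G <- balancedBCEGrad(hf$logits, msks[[ix]], pw)
          hb <- headBackward(head, hf$cache, G, nTok)
          eb <- encoderBackward(encoder, adapters, fw$cache,
                                hb$dStageOutputs)
          grads <- addNested(grads, list(A = eb$adapterGrads,
                                         H = hb$grads))
        }
        grads <- scaleNested(grads, 1 / length(bt))
        epochLoss <- epochLoss + batchLoss
        if (config$learningRate > 0) {
          upd <- adamStep(params, grads, state, config$learningRate)
          params <- upd$params
          state <- upd$state
        }
      }
      lossHistory[epoch] <- epochLoss / K
    }
  })
  adapters$stages <- params$A
  head$params <- params$H
  structure(list(encoder = encoder, adapters = adapters, head = head,
                 config = config, lossHistory = lossHistory),
            class = "cryofslModel")
}

#' @export
print.cryofslModel <- function(x, ...) {
  cat(sprintf(
    "cryofslModel: %d trainable values, %d epoch(s), final loss %.4g\n",
    countTrainableParams(x), length(x$lossHistory),
    if (length(x$lossHistory)) x$lossHistory[length(x$lossHistory)]
    else NA_real_))
  invisible(x)
}

#' Predict a probability mask for a micrograph
#'
#' The micrograph is resized to the model's working resolution,
#' standardized, passed through the adapted encoder and decoder head, and
#' the sigmoid probabilities are bilinearly resized back to the
#' micrograph's native shape.
#'
#' @param model a \code{"cryofslModel"} (possibly untrained).
#' @param micrograph a \linkS4class{Micrograph} or numeric matrix.
#' @return A probability \linkS4class{SegmentationMask} of the
#'   micrograph's native shape.
#' @export
predictMask <- function(model, micrograph) {
  stopifnot(inherits(model, "cryofslModel"))
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels
         else as.matrix(micrograph)
  native <- dim(img)
  sz <- c(model$config$inputSize, model$config$inputSize)
  work <- standardizeMatrix(resizeBilinear(img, sz))
  shapes <- encoderStageShapes(model$encoder, sz)
  fw <- encoderForward(model$encoder, work, adapters = model$adapters)
  hf <- headForward(model$head, fw$stageOutputs, shapes, sz)
  prob <- sigmoid(hf$logits)
  prob <- resizeBilinear(prob, native)
  SegmentationMask(pmin(pmax(prob, 0), 1), kind = "probability")
}
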