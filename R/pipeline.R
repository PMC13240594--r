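# Pipeline stages behind the command-line entry point: synth, train, pick,
# evaluate, compare. Each stage is an ordinary function over the package's
# module surface; one global seed flows into every stochastic component.

encoderFromConfig <- function(config) {
  ec <- config$encoder
  if (!identical(ec$name, "surrogate"))
    stop("encoder '", ec$name, "' requires an external checkpoint; ",
         "only the built-in 'surrogate' encoder is self-contained",
         call. = FALSE)
  buildSurrogateEncoder(ec$stage_dims, ec$stage_depths, ec$patch_stride,
                        seed = ec$seed)
}

synthSpecFromConfig <- function(config, seed) {
  sc <- config$synth
  syntheticSpec(imageShape = sc$image_shape, nParticles = sc$n_particles,
                diameterPx = sc$diameter_px,
                diameterJitter = sc$diameter_jitter, snr = sc$snr,
                minSeparation = sc$min_separation,
                allowOverlap = sc$allow_overlap, seed = seed)
}

postprocessFromConfig <- function(config) {
  pc <- config$postprocess
  postprocessConfig(expectedDiameterPx = pc$expected_diameter_px,
                    threshold = pc$threshold, areaRange = pc$area_range,
                    minCircularity = pc$min_circularity,
                    peakScales = pc$peak_scales,
                    minPeakDistanceFrac = pc$min_peak_distance_frac,
                    minSeparationFrac = pc$min_separation_frac,
                    dualPass = pc$dual_pass, dropBorder = pc$drop_border)
}

trainConfigFromConfig <- function(config) {
  tc <- config$train
  trainConfig(inputSize = tc$input_size, batchSize = tc$batch_size,
              learningRate = tc$learning_rate, maxEpochs = tc$max_epochs,
              seed = config$seed, posWeightMode = tc$pos_weight_mode,
              posWeight = tc$pos_weight, threshold = tc$threshold,
              headChannels = tc$head_channels)
}

stageSynth <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  n <- config$synth$n_items
  manifest <- data.frame(item = character(), image = character(),
                         mask = character(), coordinates = character())
  for (i in seq_len(n)) {
    out <- simulateMicrograph(synthSpecFromConfig(config,
                                                  config$seed + i - 1L))
    stem <- sprintf("item_%03d", i)
    img <- file.path(outDir, paste0(stem, ".mrc"))
    msk <- file.path(outDir, paste0(stem, "_mask.png"))
    str <- file.path(outDir, paste0(stem, "_gt.star"))
    writeMRC(out$micrograph, img)
    writeMaskPNG(out$mask, msk)
    gt <- out$particles
    writeStar(gt, str)
    manifest <- rbind(manifest, data.frame(item = stem, image = img,
                                           mask = msk, coordinates = str))
  }
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  logMsg(config, "synth: wrote ", n, " item(s) to ", outDir)
  invisible(manifest)
}

readTrainingItems <- function(imagesDir, masksDir) {
  imgs <- sort(list.files(imagesDir, pattern = "\\.(mrc|map|tif|tiff|png)$",
                          full.names = TRUE))
  imgs <- imgs[!grepl("_mask\\.png$", imgs)]
  if (!length(imgs))
    stop("no micrographs found in ", imagesDir, call. = FALSE)
  lapply(imgs, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    mf <- file.path(masksDir, paste0(stem, "_mask.png"))
    if (!file.exists(mf))
      mf <- file.path(masksDir, paste0(stem, ".png"))
    if (!file.exists(mf))
      stop("no mask found for ", stem, " in ", masksDir, call. = FALSE)
    mg <- readMicrograph(f)
    mv <- (readMicrograph(mf)@pixels > 127) * 1
    list(micrograph = mg, mask = SegmentationMask(mv, kind = "binary"),
         particles = ParticleSet(referenceShape = dim(mg@pixels),
                                 provenance = "ground_truth"))
  })
}

stageTrain <- function(config, imagesDir, masksDir, modelPath) {
  items <- readTrainingItems(imagesDir, masksDir)
  dataset <- FewShotDataset(items)
  encoder <- encoderFromConfig(config)
  adapters <- buildAdapterStack(adapterStackConfig(
    stageDims = encoder$stageDims, stageDepths = encoder$stageDepths,
    reduction = config$train$adapter_reduction,
    fftCutoffFraction = config$adapter$fft_cutoff_fraction,
    seed = config$seed))
  tc <- trainConfigFromConfig(config)
  logMsg(config, "train: K=", dataset@K, ", ",
         countTrainableParams(adapters) + 0L, "+head trainable values")
  model <- trainFewShot(dataset, encoder, adapters, config = tc)
  ckpt <- list(adapters = model$adapters, headParams = model$head$params,
               headChannels = model$head$channels,
               encoder = config$encoder, train = tc,
               lossHistory = model$lossHistory)
  dir.create(dirname(modelPath), recursive = TRUE, showWarnings = FALSE)
  saveRDS(ckpt, modelPath)
  logMsg(config, "train: final loss ",
         signif(model$lossHistory[length(model$lossHistory)], 4),
         "; checkpoint at ", modelPath)
  invisible(modelPath)
}

loadModelCheckpoint <- function(modelPath) {
  if (!file.exists(modelPath))
    stop("model checkpoint not found: ", modelPath, call. = FALSE)
  ckpt <- readRDS(modelPath)
  encoder <- buildSurrogateEncoder(ckpt$encoder$stage_dims,
                                   ckpt$encoder$stage_depths,
                                   ckpt$encoder$patch_stride,
                                   seed = ckpt$encoder$seed)
  head <- buildDecoderHead(encoder$stageDims, ckpt$headChannels)
  head$params <- ckpt$headParams
  structure(list(encoder = encoder, adapters = ckpt$adapters, head = head,
                 config = ckpt$train, lossHistory = ckpt$lossHistory),
            class = "cryofslModel")
}

stagePick <- function(config, modelPath, imagesDir, outDir) {
  model <- loadModelCheckpoint(modelPath)
  pc <- postprocessFromConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  imgs <- sort(list.files(imagesDir, pattern = "\\.(mrc|map|tif|tiff|png)$",
                          full.names = TRUE))
  imgs <- imgs[!grepl("_mask\\.png$", imgs)]
  if (!length(imgs))
    stop("no micrographs found in ", imagesDir, call. = FALSE)
  for (f in imgs) {
    mg <- readMicrograph(f)
    prob <- predictMask(model, mg)
    ps <- masksToParticles(prob, pc)
    stem <- tools::file_path_sans_ext(basename(f))
    writeStar(ps, file.path(outDir, paste0(stem, ".star")))
    writeMaskPNG(prob, file.path(outDir, paste0(stem, "_prob.png")))
    logMsg(config, "pick: ", stem, " -> ", nParticles(ps), " particle(s)")
  }
  invisible(outDir)
}

stageEvaluate <- function(config, predDir, gtDir, outPath) {
  preds <- sort(list.files(predDir, pattern = "\\.star$",
                           full.names = TRUE))
  if (!length(preds)) stop("no predictions in ", predDir, call. = FALSE)
  radius <- config$evaluate$match_radius_frac *
    config$postprocess$expected_diameter_px
  rows <- lapply(preds, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    gtf <- file.path(gtDir, paste0(stem, "_gt.star"))
    if (!file.exists(gtf)) gtf <- file.path(gtDir, paste0(stem, ".star"))
    if (!file.exists(gtf))
      stop("no ground truth for ", stem, " in ", gtDir, call. = FALSE)
    pred <- readStar(f, diameter = config$postprocess$expected_diameter_px)
    gt <- readStar(gtf, provenance = "ground_truth",
                   diameter = config$postprocess$expected_diameter_px)
    cbind(data.frame(micrograph = stem),
          evaluatePicking(pred, gt, radius))
  })
  tab <- do.call(rbind, rows)
  dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(tab, outPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  logMsg(config, "evaluate: mean F1 ", signif(mean(tab$f1), 4), " over ",
         nrow(tab), " micrograph(s)")
  invisible(tab)
}

stageCompare <- function(config, metricsPath, reference, outPath) {
  tab <- utils::read.table(metricsPath, sep = "\t", header = TRUE)
  report <- compareMethods(tab, reference)
  dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report, outPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(report)
}

#' Run one pipeline stage
#'
#' Dispatches to the stage implementations behind the command-line
#' interface. Stage-specific arguments: \code{synth} needs \code{out};
#' \code{train} needs \code{images}, \code{masks}, \code{model};
#' \code{pick} needs \code{model}, \code{images}, \code{out};
#' \code{evaluate} needs \code{pred}, \code{gt}, \code{out};
#' \code{compare} needs \code{metrics}, \code{reference}, \code{out}.
#'
#' @param stage one of "synth", "train", "pick", "evaluate", "compare".
#' @param config a \code{\link{loadConfig}} result.
#' @param ... stage-specific paths (see above).
#' @return stage result, invisibly.
#' @export
runPipeline <- function(stage = c("synth", "train", "pick", "evaluate",
                                  "compare"),
                        config = loadConfig(), ...) {
  stage <- match.arg(stage)
  args <- list(...)
  get0 <- function(k) {
    if (is.null(args[[k]]))
      stop("stage '", stage, "' requires argument '", k, "'",
           call. = FALSE)
    args[[k]]
  }
  switch(stage,
    synth = stageSynth(config, get0("out")),
    train = stageTrain(config, get0("images"), get0("masks"),
                       get0("model")),
    pick = stagePick(config, get0("model"), get0("images"), get0("out")),
    evaluate = stageEvaluate(config, get0("pred"), get0("gt"),
                             get0("out")),
    compare = stageCompare(config, get0("metrics"), get0("reference"),
                           get0("out")))
}
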