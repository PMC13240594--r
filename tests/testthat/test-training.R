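test_that("balanced BCE matches hand-evaluated cases", {
  z <- matrix(0, 10, 10)
  t <- matrix(0, 10, 10); t[1:5, ] <- 1
  expect_equal(balancedBCE(z, t, posWeight = 1), log(2), tolerance = 1e-12)
  # 2x2 hand case: z = 0, one positive pixel, posWeight 3
  expect_equal(balancedBCE(matrix(0, 2, 2), matrix(c(1, 0, 0, 0), 2, 2),
                           posWeight = 3),
               1.5 * log(2), tolerance = 1e-12)
  # saturated logits
  zs <- matrix(-20, 8, 8); ts <- matrix(0, 8, 8)
  zs[1:2, ] <- 20; ts[1:2, ] <- 1
  expect_lt(balancedBCE(zs, ts), 1e-6)
  expect_error(balancedBCE(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(balancedBCE(matrix(0, 2, 2), matrix(0.5, 2, 2)), "binary")
})

test_that("BCE gradient matches finite differences", {
  set.seed(5)
  z <- matrix(rnorm(16), 4)
  t <- matrix(rbinom(16, 1, 0.4), 4)
  g <- cryofsl:::balancedBCEGrad(z, t, posWeight = 2.5)
  eps <- 1e-6
  for (i in c(1, 7, 16)) {
    z2 <- z; z2[i] <- z[i] + eps
    z3 <- z; z3[i] <- z[i] - eps
    num <- (balancedBCE(z2, t, 2.5) - balancedBCE(z3, t, 2.5)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("adapter and head gradients match finite differences", {
  enc <- buildSurrogateEncoder(c(6, 10), c(2, 1), patchStride = 2,
                               seed = 3)
  ad <- buildAdapterStack(adapterStackConfig(stageDims = c(6, 10),
                                             stageDepths = c(2, 1),
                                             reduction = 2, seed = 5))
  set.seed(42)
  ad$stages <- cryofsl:::mapNested(function(x)
    x + rnorm(length(x), sd = 0.05), ad$stages)
  head <- buildDecoderHead(c(6, 10), channels = 3, seed = 7)
  head$params$ho <- matrix(rnorm(3, sd = 0.3), 3, 1)
  img <- matrix(rnorm(16 * 16), 16)
  tgt <- matrix(rbinom(16 * 16, 1, 0.3), 16)
  shapes <- encoderStageShapes(enc, c(16, 16))
  streams <- prepareFFTStream(img, shapes)
  nTok <- vapply(shapes, prod, 0)
  lossOf <- function() {
    fw <- cryofsl:::encoderForward(enc, img, adapters = ad,
                                   fftStreams = streams)
    hf <- cryofsl:::headForward(head, fw$stageOutputs, shapes, c(16, 16))
    balancedBCE(hf$logits, tgt, posWeight = 2)
  }
  fw <- cryofsl:::encoderForward(enc, img, adapters = ad,
                                 fftStreams = streams, keepCache = TRUE)
  hf <- cryofsl:::headForward(head, fw$stageOutputs, shapes, c(16, 16),
                              keepCache = TRUE)
  G <- cryofsl:::balancedBCEGrad(hf$logits, tgt, posWeight = 2)
  hb <- cryofsl:::headBackward(head, hf$cache, G, nTok)
  eb <- cryofsl:::encoderBackward(enc, ad, fw$cache, hb$dStageOutputs)
  eps <- 1e-6
  fdCheck <- function(getter, setter, analytic, k) {
    p <- getter()
    p2 <- p; p2[k] <- p[k] + eps; setter(p2)
    up <- lossOf()
    p2[k] <- p[k] - eps; setter(p2)
    dn <- lossOf()
    setter(p)
    expect_equal(analytic[k], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
  fdCheck(function() ad$stages[[1]]$E,
          function(v) ad$stages[[1]]$E <<- v, eb$adapterGrads[[1]]$E, 3)
  fdCheck(function() ad$stages[[2]]$blocks[[1]]$U,
          function(v) ad$stages[[2]]$blocks[[1]]$U <<- v,
          eb$adapterGrads[[2]]$blocks[[1]]$U, 2)
  fdCheck(function() ad$stages[[1]]$wF,
          function(v) ad$stages[[1]]$wF <<- v, eb$adapterGrads[[1]]$wF, 1)
  fdCheck(function() head$params$proj[[1]],
          function(v) head$params$proj[[1]] <<- v, hb$grads$proj[[1]], 5)
  fdCheck(function() head$params$ho,
          function(v) head$params$ho <<- v, hb$grads$ho, 2)
})

test_that("zero learning rate is a null update", {
  spec <- syntheticSpec(nParticles = 4, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 20, seed = 12)
  ds <- simulateFewShotDataset(spec, 2)
  enc <- tinyEncoder()
  cfg <- trainConfig(inputSize = 64L, learningRate = 0, maxEpochs = 5L,
                     seed = 2, headChannels = 4L)
  ad0 <- tinyAdapters(seed = 2)
  hd0 <- buildDecoderHead(enc$stageDims, channels = 4L, seed = 2)
  model <- trainFewShot(ds, enc, adapters = ad0, head = hd0, config = cfg)
  expect_identical(model$adapters$stages, ad0$stages)
  expect_identical(model$head$params, hd0$params)
  expect_length(model$lossHistory, 5L)
})

test_that("training is deterministic and never touches the encoder", {
  spec <- syntheticSpec(nParticles = 5, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 18, seed = 3)
  ds <- simulateFewShotDataset(spec, 3)
  enc <- tinyEncoder()
  encBefore <- serialize(enc, NULL)
  cfg <- trainConfig(inputSize = 64L, learningRate = 1e-3,
                     maxEpochs = 15L, seed = 9, headChannels = 4L)
  m1 <- trainFewShot(ds, enc, config = cfg)
  expect_identical(serialize(enc, NULL), encBefore)
  expect_identical(serialize(m1$encoder, NULL), encBefore)
  m2 <- trainFewShot(ds, enc, config = cfg)
  expect_identical(m1$lossHistory, m2$lossHistory)
  expect_identical(m1$head$params, m2$head$params)
})

test_that("loss decreases markedly on a separable synthetic task", {
  spec <- syntheticSpec(nParticles = 6, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 16, seed = 21)
  ds <- simulateFewShotDataset(spec, 3)
  enc <- tinyEncoder()
  cfg <- trainConfig(inputSize = 64L, learningRate = 1e-3,
                     maxEpochs = 100L, seed = 4, headChannels = 8L)
  model <- trainFewShot(ds, enc, config = cfg)
  lh <- model$lossHistory
  expect_lt(lh[length(lh)], 0.5 * lh[1])
  # smoothed curve is close to monotone non-increasing
  sm <- stats::filter(lh, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_gte(mean(diff(sm) <= 1e-6), 0.95)
})

test_that("trainer rejects empty or non-binary inputs", {
  spec <- syntheticSpec(nParticles = 3, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 20, seed = 8)
  ds <- simulateFewShotDataset(spec, 1)
  ds@items[[1]]$mask@values[1, 1] <- 0.5
  expect_error(trainFewShot(ds, tinyEncoder(),
                            config = trainConfig(inputSize = 64L)),
               "binary")
  expect_error(FewShotDataset(list()), "at least one")
})

test_that("posWeight auto mode balances and degrades gracefully", {
  msk <- matrix(0, 10, 10); msk[1, 1:2] <- 1
  expect_equal(cryofsl:::autoPosWeight(list(msk)), 49)
  expect_equal(cryofsl:::autoPosWeight(list(matrix(1, 4, 4) * 0 + 1,
                                            matrix(1, 4, 4))) |>
                 suppressWarnings(), 1)
  expect_warning(cryofsl:::autoPosWeight(list(matrix(0, 4, 4))),
                 "degenerate")
  big <- matrix(0, 100, 100); big[1, 1] <- 1
  expect_equal(cryofsl:::autoPosWeight(list(big)), 100)  # clipped
})

test_that("predictMask honors contracts at and away from native size", {
  spec <- syntheticSpec(nParticles = 5, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 18, seed = 33)
  ds <- simulateFewShotDataset(spec, 2)
  enc <- tinyEncoder()
  cfg <- trainConfig(inputSize = 64L, learningRate = 1e-3,
                     maxEpochs = 2L, seed = 1, headChannels = 4L)
  model <- trainFewShot(ds, enc, config = cfg)
  # fresh zero-initialized head: uniform 0.5
  fresh <- model
  fresh$adapters <- tinyAdapters(seed = 9)
  fresh$head <- buildDecoderHead(enc$stageDims, channels = 4L, seed = 9)
  pm <- predictMask(fresh, ds@items[[1]]$micrograph)
  expect_true(all(abs(maskValues(pm) - 0.5) < 1e-12))
  # odd input shape: resized internally, output at native shape
  odd <- Micrograph(matrix(rnorm(50 * 70), 50, 70))
  out <- predictMask(model, odd)
  expect_equal(dim(maskValues(out)), c(50L, 70L))
  expect_true(all(maskValues(out) >= 0 & maskValues(out) <= 1))
  expect_equal(maskKind(out), "probability")
})

test_that("a briefly trained model separates particles from background", {
  spec <- syntheticSpec(nParticles = 6, imageShape = c(64, 64),
                        diameterPx = 10, minSeparation = 16, seed = 50)
  ds <- simulateFewShotDataset(spec, 3)
  cfg <- trainConfig(inputSize = 64L, learningRate = 1e-3,
                     maxEpochs = 80L, seed = 6, headChannels = 8L)
  model <- trainFewShot(ds, tinyEncoder(), config = cfg)
  s2 <- spec; s2$seed <- 999
  held <- simulateMicrograph(s2)
  prob <- maskValues(predictMask(model, held$micrograph))
  msk <- maskValues(held$mask)
  expect_gt(mean(prob[msk == 1]), mean(prob[msk == 0]))
})
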