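test_that("high-pass filter has zero DC gain and zero-mean output", {
  out <- highpassFilter(matrix(5, 32, 32))
  expect_lt(max(abs(out)), 1e-8)
  set.seed(8)
  img <- matrix(rnorm(48 * 48), 48)
  expect_lt(abs(sum(highpassFilter(img))), 1e-6 * 48 * 48)
  expect_error(highpassFilter(matrix(c(NA, rnorm(15)), 4, 4)), "finite")
  expect_error(highpassFilter(img, 0), "cutoffFraction")
  expect_error(highpassFilter(img, 1), "cutoffFraction")
})

test_that("high-pass filter matches the direct FFT-mask-inverse oracle", {
  set.seed(21)
  for (rep in 1:10) {
    img <- matrix(rnorm(32 * 32), 32)
    got <- highpassFilter(img, 0.25)
    ref <- oracleHighpass(img, 0.25)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("high-frequency content passes nearly unchanged", {
  checker <- outer(1:64, 1:64, function(r, c) (-1)^(r + c))
  out <- highpassFilter(checker, 0.25)
  expect_gt(cor(as.vector(out), as.vector(checker)), 0.99)
})

test_that("FFT streams honor stage shapes and zero-mean normalization", {
  shapes <- list(c(32L, 32L), c(16L, 16L), c(8L, 8L), c(4L, 4L))
  set.seed(2)
  streams <- prepareFFTStream(matrix(rnorm(128 * 128), 128), shapes)
  expect_equal(lapply(streams, dim), lapply(shapes, as.integer))
  for (s in streams) expect_lt(abs(mean(s)), 1e-6)
  constant <- prepareFFTStream(matrix(3, 128, 128), shapes)
  for (s in constant) expect_true(all(s == 0))
  impulse <- matrix(0, 128, 128); impulse[64, 64] <- 1
  for (s in prepareFFTStream(impulse, shapes))
    expect_lt(abs(mean(s)), 1e-6)
  expect_error(prepareFFTStream(matrix(0, 128, 128), list(c(30L, 30L))),
               "downsampling")
})

test_that("adapter stack allocation matches the stage layout", {
  cfg <- adapterStackConfig()    # 144/288/576/1152, depths 2/6/36/4
  stack <- buildAdapterStack(cfg)
  expect_equal(sum(vapply(stack$stages, function(s) length(s$blocks), 0L)),
               48L)
  expect_equal(length(stack$stages), 4L)
  expect_equal(stack$bottleneck, c(4L, 9L, 18L, 36L))
  for (s in stack$stages) {
    expect_true(all(s$S == 0))     # shared up-projection zero-initialized
    expect_true(all(s$bS == 0))
  }
  one <- buildAdapterStack(adapterStackConfig(stageDims = 32L,
                                              stageDepths = 1L,
                                              reduction = 32L))
  expect_equal(dim(one$stages[[1]]$blocks[[1]]$U), c(1L, 1L))
  expect_error(buildAdapterStack(adapterStackConfig(stageDims = 16L,
                                                    stageDepths = 1L,
                                                    reduction = 32L)),
               "bottleneck")
  clamped <- buildAdapterStack(adapterStackConfig(stageDims = 16L,
                                                  stageDepths = 1L,
                                                  reduction = 32L),
                               clampBottleneck = TRUE)
  expect_equal(clamped$bottleneck, 1L)
})

test_that("adapterForward is the residual bottleneck composition", {
  ad <- tinyAdapters()
  feat <- matrix(rnorm(64 * 8), 64, 8)
  fft <- rnorm(64)
  # zero-initialized shared layer: exact identity
  expect_identical(adapterForward(feat, fft, ad, 1, 1), feat)
  # scalar hand-composition: all weights 1, biases 0, feat = 0, fft = 0
  ad1 <- buildAdapterStack(adapterStackConfig(stageDims = 1L,
                                              stageDepths = 1L,
                                              reduction = 1L))
  ad1$stages[[1]]$E[] <- 1
  ad1$stages[[1]]$wF[] <- 1
  ad1$stages[[1]]$S[] <- 1
  ad1$stages[[1]]$blocks[[1]]$U[] <- 1
  out <- adapterForward(matrix(0, 1, 1), 0, ad1, 1, 1)
  expect_equal(out[1, 1], 0)                     # GELU(0) * 1 + 0
  ad1$stages[[1]]$blocks[[1]]$bU[] <- 1
  out2 <- adapterForward(matrix(0, 1, 1), 0, ad1, 1, 1)
  expect_equal(out2[1, 1], 1 * pnorm(1))         # GELU(1) through S = 1
  # shape preservation and index errors
  stack <- tinyAdapters()
  f2 <- matrix(rnorm(16 * 16), 16, 16)
  expect_equal(dim(adapterForward(f2, rnorm(16), stack, 2, 1)),
               c(16L, 16L))
  expect_error(adapterForward(f2, rnorm(16), stack, 5, 1), "stage index")
  expect_error(adapterForward(f2, rnorm(16), stack, 1, 3), "block index")
  expect_error(adapterForward(f2, rnorm(16), stack, 1, 1),
               "does not match")
})

test_that("surrogate encoder honors the stage-shape contract and seed", {
  enc <- tinyEncoder()
  shapes <- encoderStageShapes(enc, c(64, 64))
  expect_equal(shapes, list(c(16L, 16L), c(8L, 8L), c(4L, 4L), c(2L, 2L)))
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64)
  o1 <- forwardFeatures(enc, img)
  o2 <- forwardFeatures(buildSurrogateEncoder(c(8, 16, 32, 64),
                                              c(1, 1, 2, 1),
                                              patchStride = 4, seed = 3),
                        img)
  expect_identical(o1$final, o2$final)
  expect_true(enc$frozen)
  expect_error(encoderStageShapes(enc, c(60, 60)), "stride")
})

test_that("zero-initialized adapters leave the encoder output untouched", {
  enc <- tinyEncoder()
  ad <- tinyAdapters()
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(rnorm(64 * 64), 64)
    plain <- forwardFeatures(enc, img)$final
    adapted <- forwardFeatures(attachAdapters(enc, ad), img)$final
    expect_lt(max(abs(plain - adapted)), 1e-6)
  }
})

test_that("random adapters modulate; detaching restores exactly", {
  enc <- tinyEncoder()
  ad <- tinyAdapters()
  for (i in seq_along(ad$stages)) {
    ad$stages[[i]]$S[] <- rnorm(length(ad$stages[[i]]$S), sd = 0.1)
  }
  set.seed(32)
  img <- matrix(rnorm(64 * 64), 64)
  plain <- forwardFeatures(enc, img)$final
  adapted <- attachAdapters(enc, ad)
  expect_gt(max(abs(forwardFeatures(adapted, img)$final - plain)), 1e-8)
  restored <- forwardFeatures(detachAdapters(adapted), img)$final
  expect_identical(restored, plain)
  # residual deviation is bounded by the product of layer operator norms
  dev <- max(abs(forwardFeatures(adapted, img)$final - plain))
  expect_true(is.finite(dev))
})

test_that("adapter mismatch against the encoder is reported by stage dims", {
  enc <- tinyEncoder()
  wrong <- buildAdapterStack(adapterStackConfig(stageDims = c(8, 16, 32, 60),
                                                stageDepths = c(1, 1, 2, 1),
                                                reduction = 4))
  expect_error(attachAdapters(enc, wrong), "stage dims")
})

test_that("trainable parameter count matches the closed form", {
  cfg <- adapterStackConfig(stageDims = c(16L, 32L), stageDepths = c(2L, 3L),
                            reduction = 4L)
  stack <- buildAdapterStack(cfg)
  D <- cfg$stageDims
  d <- D %/% 4L
  depths <- cfg$stageDepths
  closed <- sum(d * (d + 1) * depths +    # unshared U + bU per block
                (D * d + d) +             # embedding projection + bias
                (d + d) +                 # fft projection + bias
                (d * D + D))              # shared up-projection + bias
  expect_equal(countTrainableParams(stack), closed)
  # frozen encoder contributes nothing, and widening it changes nothing
  expect_equal(countTrainableParams(tinyEncoder()), 0L)
  model <- list(adapters = stack,
                head = buildDecoderHead(c(16, 32), channels = 4))
  class(model) <- "cryofslModel"
  wide <- model
  expect_equal(countTrainableParams(model),
               closed + countTrainableParams(model$head))
})
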