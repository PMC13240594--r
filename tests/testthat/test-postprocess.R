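mkMask <- function(m) SegmentationMask(m, kind = "binary")

test_that("binarization is strict and monotone in the threshold", {
  u <- SegmentationMask(matrix(0.5, 16, 16))
  expect_equal(sum(maskValues(binarizeMask(u, 0.5))), 0)
  one <- matrix(0, 16, 16); one[4, 9] <- 0.9
  expect_equal(sum(maskValues(binarizeMask(SegmentationMask(one), 0.5))), 1)
  set.seed(3)
  p <- SegmentationMask(matrix(runif(32 * 32), 32))
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    sum(maskValues(binarizeMask(p, th))), 0)
  expect_true(all(diff(areas) <= 0))
  low <- binarizeMask(p, 1e-12)
  expect_equal(sum(maskValues(low)), sum(maskValues(p) > 1e-12))
})

test_that("distance map matches the brute-force oracle", {
  z <- matrix(0, 20, 20)
  expect_true(all(distanceMap(mkMask(z)) == 0))
  single <- z; single[7, 9] <- 1
  dm <- distanceMap(mkMask(single))
  expect_equal(dm[7, 9], 1)
  expect_equal(sum(dm > 0), 1)
  # centered disk radius 10 in 64 x 64
  disk <- outer(1:64, 1:64, function(r, c)
    ((r - 32.5)^2 + (c - 32.5)^2 <= 100) * 1)
  dmd <- distanceMap(mkMask(disk))
  expect_gte(max(dmd), 9.0)
  expect_lte(max(dmd), 10.5)
  set.seed(14)
  v <- matrix(rbinom(24 * 24, 1, 0.4), 24)
  expect_equal(distanceMap(mkMask(v)), oracleDistance(v), tolerance = 1e-6)
})

test_that("peak detection finds separated and overlapping disk centers", {
  cfg <- postprocessConfig(expectedDiameterPx = 16)
  canvas <- matrix(0, 96, 96)
  addDisk <- function(m, cx, cy, r) {
    m | outer(1:96, 1:96, function(rr, cc)
      (rr - 1 - cy)^2 + (cc - 1 - cx)^2 <= r^2)
  }
  two <- addDisk(addDisk(matrix(FALSE, 96, 96), 25, 40, 8), 65, 40, 8) * 1
  dm <- distanceMap(mkMask(two))
  pk <- detectPeaks(dm, cfg)
  expect_equal(nrow(pk), 2L)
  dc <- pmin(sqrt((pk$x - 25)^2 + (pk$y - 40)^2),
             sqrt((pk$x - 65)^2 + (pk$y - 40)^2))
  expect_true(all(dc <= 2))
  expect_equal(nrow(detectPeaks(matrix(0, 32, 32), cfg)), 0L)
  pair <- simulateOverlappingPair(16, 0.6 * 16, seed = 1)
  pk2 <- detectPeaks(distanceMap(pair$mask), cfg)
  expect_equal(nrow(pk2), 2L)
})

test_that("watershed splits an overlapping pair into two plausible areas", {
  pair <- simulateOverlappingPair(16, 10, seed = 5)
  dm <- distanceMap(pair$mask)
  cfg <- postprocessConfig(expectedDiameterPx = 16)
  seeds <- detectPeaks(dm, cfg)
  ws <- watershedSplit(pair$mask, seeds, dm)
  st <- regionStats(ws)
  expect_equal(nrow(st), 2L)
  expect_equal(sum(st$area), sum(maskValues(pair$mask)))
  for (a in st$area)
    expect_lt(abs(a - pi * 64) / (pi * 64), 0.35)
  # single disk, single seed: conservation
  disk <- outer(1:48, 1:48, function(r, c)
    ((r - 24)^2 + (c - 24)^2 <= 81) * 1)
  dmd <- distanceMap(mkMask(disk))
  ws1 <- watershedSplit(mkMask(disk), data.frame(x = 23, y = 23), dmd)
  expect_equal(regionStats(ws1)$area, sum(disk))
  # no seeds: no labels
  ws0 <- watershedSplit(mkMask(disk),
                        data.frame(x = numeric(), y = numeric()), dmd)
  expect_equal(nrow(regionStats(ws0)), 0L)
  expect_warning(
    watershedSplit(mkMask(disk), data.frame(x = 1, y = 1), dmd),
    "background")
})

test_that("geometric filter keeps disks and rejects bars and specks", {
  cfg <- postprocessConfig(expectedDiameterPx = 20)
  canvas <- matrix(0L, 64, 64)
  disk <- outer(1:64, 1:64, function(r, c)
    ((r - 20)^2 + (c - 20)^2 <= 100))
  canvas[disk] <- 1L
  canvas[50:52, 10:39] <- 2L           # 3 x 30 bar
  canvas[5, 60] <- 3L                  # single pixel
  regions <- new("LabeledRegions", labels = canvas,
                 stats = cryofsl:::computeRegionStats(canvas))
  st <- regionStats(regions)
  expect_gte(st$circularity[st$label == 1], 0.85)
  expect_lt(st$circularity[st$label == 2], 0.6)
  kept <- geometricFilter(regions, cfg)
  expect_equal(nrow(regionStats(kept)), 1L)
  expect_equal(regionStats(kept)$area, sum(disk))
  expect_equal(sort(unique(as.vector(regionLabels(kept)))), c(0L, 1L))
})

test_that("dual-pass localization centers a clean disk to the pixel", {
  spec <- syntheticSpec(nParticles = 1, imageShape = c(64, 64),
                        diameterPx = 16, seed = 2)
  out <- simulateMicrograph(spec)
  cfg <- postprocessConfig(expectedDiameterPx = 16)
  ps <- dualPassLocalize(out$mask, config = cfg)
  expect_equal(nParticles(ps), 1L)
  cc <- particles(ps); gt <- particles(out$particles)
  expect_lt(sqrt((cc$x - gt$x)^2 + (cc$y - gt$y)^2), 1)
})

test_that("dual pass recovers at least as many particles as single pass", {
  for (s in c(3, 11)) {
    spec <- syntheticSpec(nParticles = 30, imageShape = c(256, 256),
                          diameterPx = 16, minSeparation = 0.8 * 16,
                          allowOverlap = TRUE, seed = s)
    out <- simulateMicrograph(spec)
    nSingle <- nParticles(masksToParticles(
      out$mask, postprocessConfig(16, dualPass = FALSE)))
    nDual <- nParticles(masksToParticles(out$mask, postprocessConfig(16)))
    expect_gte(nDual, nSingle)
  }
})

test_that("output centers always respect the deduplication radius", {
  cfg <- postprocessConfig(expectedDiameterPx = 12)
  minSep <- cfg$minSeparationFrac * 12
  set.seed(6)
  for (rep in 1:5) {
    blob <- (matrix(runif(96 * 96), 96) > 0.72) * 1
    blob <- maskValues(binarizeMask(
      SegmentationMask(cryofsl:::gaussianSmooth(blob, 2)), 0.3))
    ps <- dualPassLocalize(mkMask(blob), config = cfg)
    cc <- particles(ps)
    if (nrow(cc) > 1) {
      dmat <- as.matrix(dist(cbind(cc$x, cc$y)))
      diag(dmat) <- Inf
      expect_gte(min(dmat), minSep)
    }
  }
})

test_that("mask-to-particle oracle: exact recovery on ground-truth masks", {
  cfg <- postprocessConfig(expectedDiameterPx = 16)
  for (s in 1:4) {
    spec <- syntheticSpec(nParticles = 25, imageShape = c(384, 384),
                          diameterPx = 16, minSeparation = 24, seed = s)
    out <- simulateMicrograph(spec)
    ps <- masksToParticles(out$mask, cfg)
    expect_equal(nParticles(ps), 25L)
    m <- matchParticles(ps, out$particles, matchRadius = 2)
    expect_equal(matchCounts(m)[["tp"]], 25L)
    expect_lte(max(matchedPairs(m)$distance), 2)
  }
  # determinism and empty input
  out <- simulateMicrograph(syntheticSpec(nParticles = 5, seed = 77))
  a <- masksToParticles(out$mask, cfg)
  b <- masksToParticles(out$mask, cfg)
  expect_identical(particles(a), particles(b))
  empty <- masksToParticles(SegmentationMask(matrix(0, 64, 64)), cfg)
  expect_equal(nParticles(empty), 0L)
})

test_that("particle scores reflect mask probability over regions", {
  spec <- syntheticSpec(nParticles = 3, imageShape = c(96, 96),
                        diameterPx = 14, minSeparation = 28, seed = 13)
  out <- simulateMicrograph(spec)
  prob <- maskValues(out$mask) * 0.9
  ps <- masksToParticles(SegmentationMask(prob), postprocessConfig(14))
  expect_equal(nParticles(ps), 3L)
  expect_true(all(abs(particles(ps)$score - 0.9) < 0.05))
  expect_true(all(abs(particles(ps)$diameter - 14) < 2))
})
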