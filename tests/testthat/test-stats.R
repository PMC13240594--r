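test_that("Shapiro gate calibrates under Gaussian and exponential draws", {
  hitsN <- hitsE <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (shapiroGate(rnorm(50))$isNormal) hitsN <- hitsN + 1L
    set.seed(s)
    if (!shapiroGate(rexp(50))$isNormal) hitsE <- hitsE + 1L
  }
  expect_gte(hitsN, 90L)
  expect_gte(hitsE, 90L)
  expect_warning(out <- shapiroGate(rep(1, 10)), "constant")
  expect_true(is.na(out$isNormal))
  expect_error(shapiroGate(c(1, 2)), "3 <= N")
})

test_that("signed-rank test matches hand cases and the base-R oracle", {
  expect_warning(deg <- wilcoxonPaired(1:10, 1:10), "zero")
  expect_equal(deg[c("statistic", "z", "p")],
               list(statistic = 0, z = 0, p = 1))
  # uniform shift, N = 20: statistic (min rank sum) is 0, p very small
  b <- seq(0.5, 10, by = 0.5)
  res <- wilcoxonPaired(b + 1, b)
  expect_equal(res$statistic, 0)
  expect_lt(res$p, 0.001)
  expect_gt(res$z, 0)
  # direction flips the z sign
  expect_lt(wilcoxonPaired(b - 1, b)$z, 0)
  # oracle: base wilcox.test normal approximation without continuity
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(30); bb <- rnorm(30)
    got <- wilcoxonPaired(a, bb)
    ref <- wilcox.test(a, bb, paired = TRUE, exact = FALSE,
                       correct = FALSE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  # tied differences still agree with the oracle's tie correction
  set.seed(4)
  a <- sample(1:4, 30, replace = TRUE)
  bb <- sample(1:4, 30, replace = TRUE)
  keep <- a != bb
  got <- suppressWarnings(wilcoxonPaired(a[keep], bb[keep]))
  ref <- suppressWarnings(wilcox.test(a[keep], bb[keep], paired = TRUE,
                                      exact = FALSE, correct = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("signed-rank type-I error is nominal under the null", {
  hits <- 0L
  for (s in 1:1000) {
    set.seed(s)
    a <- rnorm(20); b <- rnorm(20)
    if (wilcoxonPaired(a, b)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 30L)   # 5% +/- 2% of 1000
  expect_lte(hits, 70L)
})

test_that("rank-biserial effect size is z over root N", {
  expect_identical(rankBiserial(2, 16), 0.5)
  expect_identical(rankBiserial(0, 7), 0)
  expect_equal(rankBiserial(-3.3, 121), -0.3, tolerance = 1e-12)
  expect_error(rankBiserial(1, 0), "N")
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.04, 30)), rep(0.04, 30))
  set.seed(2)
  p <- runif(40)
  got <- bhAdjust(p)
  expect_equal(got, p.adjust(p, method = "BH"), tolerance = 1e-12)
  expect_true(all(got >= p))
  expect_true(all(got <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

simulateMetricTable <- function(nMethods = 5, nDatasets = 6, nMics = 12,
                                shift = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ds in paste0("ds", seq_len(nDatasets))) {
    base <- pmin(pmax(rnorm(nMics, 0.7, 0.1), 0), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      method = "reference", dataset = ds,
      micrograph = paste0(ds, "_m", seq_len(nMics)),
      precision = base, recall = base)
    for (mt in paste0("method", seq_len(nMethods))) {
      noise <- rnorm(nMics, 0, 0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mt, dataset = ds,
        micrograph = paste0(ds, "_m", seq_len(nMics)),
        precision = pmin(pmax(base - shift + noise, 0), 1),
        recall = pmin(pmax(base - shift + noise, 0), 1))
    }
  }
  do.call(rbind, rows)
}

test_that("compareMethods produces 30 tests per metric and finds shifts", {
  tab <- simulateMetricTable(shift = 0.2, seed = 3)
  rep <- compareMethods(tab, reference = "reference")
  expect_equal(sum(rep$metric == "precision"), 30L)
  expect_equal(sum(rep$metric == "recall"), 30L)
  worse <- rep[rep$metric == "recall", ]
  expect_true(all(worse$pAdjusted < 0.05))
  expect_true(all(worse$effectSize < 0))
  expect_true(all(worse$pAdjusted >= worse$p))
})

test_that("compareMethods is degenerate-safe and flags tiny samples", {
  tab <- simulateMetricTable(nMethods = 1, nDatasets = 1, nMics = 10,
                             shift = 0, seed = 5)
  tab$precision[tab$method == "method1"] <-
    tab$precision[tab$method == "reference"]
  tab$recall[tab$method == "method1"] <-
    tab$recall[tab$method == "reference"]
  rep <- suppressWarnings(compareMethods(tab, reference = "reference"))
  expect_true(all(rep$p == 1))
  expect_true(all(rep$effectSize == 0))
  small <- simulateMetricTable(nMethods = 1, nDatasets = 1, nMics = 3,
                               seed = 6)
  rep2 <- compareMethods(small, reference = "reference")
  expect_true(all(rep2$untestable))
  expect_error(compareMethods(small, reference = "nope"), "reference")
})

test_that("full comparison pipeline controls type-I error under the null", {
  hits <- 0L
  total <- 0L
  for (s in 1:120) {
    tab <- simulateMetricTable(nMethods = 2, nDatasets = 2, nMics = 10,
                               shift = 0, seed = 4000 + s)
    rep <- suppressWarnings(compareMethods(tab, reference = "reference",
                                           metrics = "precision"))
    hits <- hits + sum(rep$p < 0.05, na.rm = TRUE)
    total <- total + sum(!rep$untestable)
  }
  expect_lte(hits / total, 0.07)
})
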