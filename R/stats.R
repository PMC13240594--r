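# Statistical comparison of picking methods: Shapiro-Wilk normality gate,
# paired Wilcoxon signed-rank test (normal approximation with tie
# correction), rank-biserial effect size r = z / sqrt(N), and
# Benjamini-Hochberg adjustment applied per metric across all
# method-by-dataset tests.

#' Shapiro-Wilk normality gate
#'
#' @param samples numeric vector, 3 <= N <= 5000.
#' @param alpha significance level for the gate (default 0.05).
#' @return list with \code{W}, \code{p} and \code{isNormal}
#'   (\code{p >= alpha}); a constant sample is non-testable and returns NA
#'   entries with a warning.
#' @export
shapiroGate <- function(samples, alpha = 0.05) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= N <= 5000 (got ", n, ")",
         call. = FALSE)
  if (stats::sd(samples) == 0) {
    warning("constant sample: normality is not testable")
    return(list(W = NA_real_, p = NA_real_, isNormal = NA))
  }
  sw <- stats::shapiro.test(samples)
  list(W = unname(sw$statistic), p = sw$p.value,
       isNormal = sw$p.value >= alpha)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Two-sided signed-rank test on the paired differences \code{a - b}.
#' Zero differences are dropped; ranks of absolute differences use midranks
#' and the variance carries the tie correction
#' \code{sum(t^3 - t) / 48}. The reported statistic is
#' \code{min(W+, W-)}; \code{z = (W+ - mu) / sigma} is signed by the
#' direction of the rank sum (positive when \code{a} tends to exceed
#' \code{b}, matching the sign of the median difference in non-degenerate
#' cases) and \code{p = 2 * pnorm(-|z|)}.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with \code{statistic}, \code{z}, \code{p} and \code{n}
#'   (pairs remaining after zero removal). All-zero differences give the
#'   degenerate result (statistic 0, z = 0, p = 1) with a warning.
#' @export
wilcoxonPaired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test is degenerate")
    return(list(statistic = 0, z = 0, p = 1, n = 0L))
  }
  if (n < 5L)
    warning("fewer than 5 non-zero differences; normal approximation is ",
            "unreliable")
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  wMinus <- n * (n + 1) / 2 - wPlus
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    warning("degenerate variance in signed-rank test")
    return(list(statistic = min(wPlus, wMinus), z = 0, p = 1, n = n))
  }
  z <- (wPlus - mu) / sqrt(sigma2)
  list(statistic = min(wPlus, wMinus), z = z,
       p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Rank-biserial effect size
#'
#' \code{r = z / sqrt(N)}, the rank-biserial correlation associated with a
#' Wilcoxon signed-rank z statistic over N paired observations.
#'
#' @param z Wilcoxon z statistic.
#' @param N number of paired observations (>= 1).
#' @return numeric effect size.
#' @examples
#' rankBiserial(2, 16)  # 0.5
#' @export
rankBiserial <- function(z, N) {
  if (!is.finite(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  z / sqrt(N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, computes \code{q_(k) = p_(k) * m / k},
#' enforces monotonicity from the largest rank down, caps at 1 and restores
#' the input order.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  ord <- order(pvals)
  q <- pvals[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Compare picking methods against a reference
#'
#' Input is a long-format metric table with one row per (method, dataset,
#' micrograph) and one column per metric. For every non-reference method,
#' dataset and metric, the per-micrograph values are paired with the
#' reference method's values on the same micrographs; a Shapiro-Wilk gate
#' on the paired differences records the normality flag, the paired
#' Wilcoxon signed-rank test is applied (the nonparametric test is used
#' throughout, as metric distributions across micrographs are typically
#' non-Gaussian), the effect size is \code{r = z / sqrt(N)}, and
#' Benjamini-Hochberg adjustment is applied jointly over all tests of the
#' same metric. Entries with fewer than 5 valid pairs are flagged
#' untestable (NA statistics).
#'
#' @param metricTable data.frame with columns \code{method},
#'   \code{dataset}, \code{micrograph} and one numeric column per metric.
#' @param reference method identifier to test against.
#' @param metrics metric column names; defaults to all numeric columns.
#' @return data.frame (one row per method x dataset x metric) with columns
#'   method, dataset, metric, n, statistic, z, p, pAdjusted, effectSize,
#'   normalDifferences, untestable.
#' @export
compareMethods <- function(metricTable, reference,
                           metrics = NULL) {
  need <- c("method", "dataset", "micrograph")
  if (!all(need %in% names(metricTable)))
    stop("metricTable needs columns method, dataset, micrograph",
         call. = FALSE)
  if (!reference %in% metricTable$method)
    stop("reference method '", reference, "' not present", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- setdiff(names(metricTable)[vapply(metricTable, is.numeric,
                                                 TRUE)],
                       need)
  }
  methods <- setdiff(unique(metricTable$method), reference)
  datasets <- unique(metricTable$dataset)
  rows <- list()
  for (met in metrics) {
    for (mth in methods) {
      for (ds in datasets) {
        refRows <- metricTable[metricTable$method == reference &
                                 metricTable$dataset == ds, ]
        cmpRows <- metricTable[metricTable$method == mth &
                                 metricTable$dataset == ds, ]
        common <- intersect(refRows$micrograph, cmpRows$micrograph)
        aVal <- cmpRows[[met]][match(common, cmpRows$micrograph)]
        bVal <- refRows[[met]][match(common, refRows$micrograph)]
        ok <- is.finite(aVal) & is.finite(bVal)
        aVal <- aVal[ok]; bVal <- bVal[ok]
        nPairs <- length(aVal)
        untestable <- nPairs < 5L
        if (untestable) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = mth, dataset = ds, metric = met, n = nPairs,
            statistic = NA_real_, z = NA_real_, p = NA_real_,
            pAdjusted = NA_real_, effectSize = NA_real_,
            normalDifferences = NA, untestable = TRUE)
          next
        }
        gate <- suppressWarnings(
          tryCatch(shapiroGate(aVal - bVal)$isNormal,
                   error = function(e) NA))
        wt <- suppressWarnings(wilcoxonPaired(aVal, bVal))
        rows[[length(rows) + 1L]] <- data.frame(
          method = mth, dataset = ds, metric = met, n = nPairs,
          statistic = wt$statistic, z = wt$z, p = wt$p,
          pAdjusted = NA_real_,
          effectSize = rankBiserial(wt$z, nPairs),
          normalDifferences = gate, untestable = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  for (met in metrics) {
    sel <- report$metric == met & !report$untestable
    if (any(sel)) report$pAdjusted[sel] <- bhAdjust(report$p[sel])
  }
  rownames(report) <- NULL
  report
}
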