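#' Karyotype summary statistics
#'
#' Mean and unbiased (n-1) variance of per-cell chromosome counts.
#'
#' @param counts integer vector of chromosomes per nucleus (n >= 2), or a
#'   data.frame with a `count` column as returned by
#'   [simulate_karyotypes()].
#' @return list with `mean`, `variance`, `n`.
#' @export
karyotype_summary <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) < 2) stop("need >= 2 cells")
  if (any(counts < 0)) stop("counts must be >= 0")
  list(mean = mean(counts), variance = stats::var(counts),
       n = length(counts))
}

#' F-test for heterogeneity of chromosome counts
#'
#' Compares cell-to-cell karyotype variance between two samples:
#' `F = var(a) / var(b)` with `df = (n_a - 1, n_b - 1)` and a two-sided
#' p-value obtained by doubling the smaller tail, capped at 1. This is the
#' variance-ratio test used to ask whether chromosome-number diversity (the
#' CIN readout) differs between conditions.
#'
#' @param a,b integer vectors of per-cell counts (each n >= 2), or
#'   data.frames with a `count` column.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
variance_f_test <- function(a, b) {
  if (is.data.frame(a)) a <- a$count
  if (is.data.frame(b)) b <- b$count
  if (length(a) < 2 || length(b) < 2) stop("both samples need n >= 2")
  vb <- stats::var(b)
  if (vb == 0) stop("denominator sample has zero variance; F undefined")
  f <- stats::var(a) / vb
  df1 <- length(a) - 1L
  df2 <- length(b) - 1L
  lower <- stats::pf(f, df1, df2)
  p <- min(1, 2 * min(lower, 1 - lower))
  list(F = f, df1 = df1, df2 = df2, p = p)
}

#' Compare event proportions between two conditions
#'
#' Fold change and risk difference of per-cell event proportions (e.g.
#' fraction of cells with micronuclei or defective anaphases), with a
#' p-value from Fisher's exact test on the 2x2 table. A zero denominator
#' proportion leaves the fold change undefined (`NA`) but the test is still
#' performed.
#'
#' @param events1,n1 events and cells scored in condition 1.
#' @param events2,n2 events and cells scored in condition 2.
#' @return list with `p1`, `p2`, `fold_change` (p1/p2), `risk_difference`
#'   (p1-p2), `p`.
#' @export
proportion_compare <- function(events1, n1, events2, n2) {
  stopifnot(events1 >= 0, events2 >= 0, events1 <= n1, events2 <= n2)
  p1 <- events1 / n1
  p2 <- events2 / n2
  tab <- matrix(c(events1, n1 - events1, events2, n2 - events2), nrow = 2)
  pv <- stats::fisher.test(tab)$p.value
  list(p1 = p1, p2 = p2,
       fold_change = if (p2 > 0) p1 / p2 else NA_real_,
       risk_difference = p1 - p2, p = pv)
}

#' Fluorescence intensity ratio of two channels
#'
#' The stable-microtubule readout: mean background-subtracted intensity of
#' the signal channel (detyrosinated tubulin) within a mask, divided by the
#' same quantity for the reference channel (total beta-tubulin). Background
#' per channel is the median of the pixels outside the mask; without a mask
#' all pixels are foreground and background is taken as 0.
#'
#' @param signal,reference numeric matrices of identical dimensions,
#'   intensities >= 0.
#' @param mask optional logical matrix (same dimensions) marking the
#'   structure of interest; must contain at least one `TRUE`.
#' @return scalar ratio.
#' @export
intensity_ratio <- function(signal, reference, mask = NULL) {
  if (!all(dim(signal) == dim(reference)))
    stop("signal and reference must have identical dimensions")
  if (any(signal < 0) || any(reference < 0))
    stop("intensities must be >= 0")
  if (is.null(mask)) {
    bg_s <- 0; bg_r <- 0
    mask <- array(TRUE, dim = dim(signal))
  } else {
    if (!all(dim(mask) == dim(signal))) stop("mask dimensions differ")
    if (!any(mask)) stop("mask is empty")
    bg_s <- if (all(mask)) 0 else stats::median(signal[!mask])
    bg_r <- if (all(mask)) 0 else stats::median(reference[!mask])
  }
  num <- mean(signal[mask]) - bg_s
  den <- mean(reference[mask]) - bg_r
  if (den == 0) stop("reference channel has zero background-subtracted mean")
  num / den
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midranks for ties. The p-value is exact (distribution of
#' U under permutation of ranks) when the smaller sample has n <= 8 and
#' there are no ties, and otherwise uses the normal approximation with tie
#' correction and continuity correction. Two-sided throughout.
#'
#' @param a,b numeric vectors (each n >= 1).
#' @return list with `U` (statistic for sample `a`), `p`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples need n >= 1")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && min(n1, n2) <= 8) {
    # exact: pwilcox gives P(U <= q) for the rank-sum U statistic
    lower <- stats::pwilcox(u, n1, n2)
    upper <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 == 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}
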