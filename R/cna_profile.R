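#' Correct GC bias in a binned read-count track
#'
#' Fits the expected count as a quadratic polynomial in GC content over
#' copy-neutral-candidate bins (bins whose raw count lies within the
#' interquartile range of all counts, so outlying copy-number states do not
#' drive the fit), then rescales each bin by `median(expected) /
#' expected(bin)`. With degenerate GC (all bins equal, so no bias is
#' identifiable) the correction is the identity and a notice is logged.
#'
#' @param track a `bin_track` (see [simulate_bin_counts()] or
#'   [read_bin_track()]) with >= 50 bins.
#' @return the track with `count` replaced by corrected counts (raw counts
#'   kept in `raw_count`) and attribute `gc_fit` recording the polynomial.
#' @export
correct_gc_bias <- function(track) {
  track <- as_bin_track(track)
  if (nrow(track) < 50)
    stop("GC correction needs >= 50 bins")
  out <- track
  out$raw_count <- track$count
  if (diff(range(track$gc)) == 0) {
    message("GC content is constant across bins; GC correction is the identity")
    attr(out, "gc_fit") <- NULL
    return(out)
  }
  q <- stats::quantile(track$count, c(0.25, 0.75), names = FALSE)
  cand <- track$count >= q[1] & track$count <= q[2]
  if (sum(cand) < 10) cand <- rep(TRUE, nrow(track))
  fit <- stats::lm(count ~ gc + I(gc^2), data = track[cand, , drop = FALSE])
  expected <- stats::predict(fit, newdata = track)
  floor_e <- 0.05 * stats::median(expected)
  expected <- pmax(expected, floor_e)
  out$count <- track$count * stats::median(expected) / expected
  attr(out, "gc_fit") <- stats::coef(fit)
  out
}

as_bin_track <- function(x) {
  need <- c("chrom", "start", "end", "gc", "count")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("expected a bin track with columns chrom, start, end, gc, count")
  if (any(x$count < 0)) stop("bin counts must be >= 0")
  x
}

#' Normalised copy-number ratio profile
#'
#' Divides (GC-corrected) bin counts by the genome-wide median corrected
#' count — the `MedianRatio` reference that defines the copy-neutral
#' zero-baseline — and takes log2. Zero-count bins are masked: they carry no
#' depth information at shallow coverage and are excluded from segmentation
#' and from downstream locus comparison rather than imputed.
#'
#' @param track a `bin_track`, normally after [correct_gc_bias()].
#' @return a `ratio_profile`: the track plus `ratio`, `log2ratio`, `masked`
#'   columns and attribute `median_ratio`.
#' @export
compute_ratio_profile <- function(track) {
  track <- as_bin_track(track)
  med <- stats::median(track$count)
  if (med <= 0) stop("median corrected count is not positive; profile unusable")
  out <- track
  out$ratio <- track$count / med
  out$masked <- track$count == 0
  out$log2ratio <- ifelse(out$masked, NA_real_, log2(out$ratio))
  attr(out, "median_ratio") <- med
  class(out) <- unique(c("ratio_profile", class(track)))
  out
}

#' Segment a ratio profile by recursive binary splitting
#'
#' Per chromosome, recursively searches the series of unmasked log2 ratios
#' for the contiguous window maximising the two-sample t-statistic between
#' the window and the rest of the segment (the circular-binary-segmentation
#' scan: a window scan detects mid-segment events that a single split point
#' cannot). A candidate is accepted when its statistic exceeds the
#' `alpha`-level threshold of a within-segment permutation null, and every
#' resulting piece keeps at least `min_bins` bins. The default
#' `alpha = 0.001` controls false breakpoints at whole-genome scale
#' (a profile spawns on the order of 100 segment tests). Segment boundaries
#' sit at bin edges so the segments tile the binned extent exactly; masked
#' bins are absorbed into the enclosing segment. Deterministic for a fixed
#' `seed` (permutations abort early once a candidate can no longer reach
#' `alpha`, which does not change the decision).
#'
#' @param profile a `ratio_profile`.
#' @param min_bins minimum unmasked bins per segment (>= 2).
#' @param alpha significance level for accepting a split; must be
#'   attainable, i.e. `alpha >= 1 / (n_perm + 1)`.
#' @param n_perm permutation count for the split null.
#' @param seed RNG seed for the permutations.
#' @return a `segment_set`: data.frame `chrom`, `start`, `end`, `n_bins`,
#'   `mean_log2` with attributes `ploidy` (unset until
#'   [call_copy_numbers()]) and `params`.
#' @export
segment_profile <- function(profile, min_bins = 3L, alpha = 0.001,
                            n_perm = 999L, seed = 1L) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (min_bins < 2) stop("`min_bins` must be >= 2")
  if (alpha < 1 / (n_perm + 1))
    stop(sprintf("alpha = %g is unattainable with %d permutations (minimum p is %g)",
                 alpha, n_perm, 1 / (n_perm + 1)))
  segs <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    keep <- !p$masked
    x <- p$log2ratio[keep]
    pos <- which(keep)
    if (length(x) == 0) {
      segs[[ch]] <- data.frame(chrom = ch, start = min(p$start),
                               end = max(p$end), n_bins = 0L,
                               mean_log2 = NA_real_)
      next
    }
    cuts <- rbs_segment(x, min_bins, alpha, n_perm,
                        child_seed(seed, match(ch, unique(profile$chrom))))
    # cuts: sorted vector of split points k (segment = (k_prev, k])
    bounds <- c(0L, cuts, length(x))
    first <- bounds[-length(bounds)] + 1L
    last <- bounds[-1]
    start <- ifelse(first == 1L, min(p$start), p$start[pos[first]])
    end <- c(start[-1], max(p$end))  # tile exactly; masked gaps absorbed left
    segs[[ch]] <- data.frame(
      chrom = ch, start = start, end = end,
      n_bins = last - first + 1L,
      mean_log2 = vapply(seq_along(first), function(i)
        mean(x[first[i]:last[i]]), numeric(1)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out,
            params = list(min_bins = min_bins, alpha = alpha,
                          n_perm = n_perm, seed = seed),
            class = c("segment_set", "data.frame"))
}

# Candidate windows (i, j] of a length-nl segment: window size >= min_bins
# and each non-empty flank >= min_bins, so every piece a cut creates is
# admissible. Returns integer vectors iv (0-based window start) and jv.
cbs_windows <- function(nl, b) {
  if (nl < 2L * b) return(NULL)
  iv <- jv <- integer(0)
  for (i in c(0L, if (b <= nl - b) seq.int(b, nl - b))) {
    js <- integer(0)
    if (i + b <= nl - b) js <- seq.int(i + b, nl - b)
    if (i > 0L && i + b <= nl) js <- c(js, nl)   # right flank empty
    js <- unique(js)
    iv <- c(iv, rep.int(i, length(js)))
    jv <- c(jv, js)
  }
  if (length(iv) == 0) return(NULL)
  list(iv = iv, jv = jv, kv = jv - iv)
}

# max squared t-statistic (window vs rest) over the candidate windows
cbs_max_stat <- function(x, w) {
  n <- length(x)
  s0 <- c(0, cumsum(x))
  tot <- s0[n + 1L]
  xbar <- tot / n
  ss_tot <- sum(x * x) - n * xbar^2
  sin_ <- s0[w$jv + 1L] - s0[w$iv + 1L]
  m_in <- sin_ / w$kv
  m_out <- (tot - sin_) / (n - w$kv)
  ss_b <- w$kv * m_in^2 + (n - w$kv) * m_out^2 - n * xbar^2
  pooled <- pmax(ss_tot - ss_b, 0) / (n - 2)
  se2 <- pooled * (1 / w$kv + 1 / (n - w$kv))
  diff2 <- (m_in - m_out)^2
  t2 <- ifelse(se2 > 0, diff2 / se2, ifelse(diff2 > 0, Inf, 0))
  i <- which.max(t2)
  list(stat = t2[i], i = w$iv[i], j = w$jv[i])
}

rbs_segment <- function(x, min_bins, alpha, n_perm, seed) {
  cuts <- integer(0)
  # stack of [lo, hi] segments to test, 1-based inclusive indices
  todo <- list(c(1L, length(x)))
  stream <- 0L
  # largest permutation-exceedance count still accepted at level alpha
  limit <- floor(alpha * (n_perm + 1)) - 1L
  while (length(todo) > 0) {
    seg <- todo[[1]]; todo <- todo[-1]
    lo <- seg[1]; hi <- seg[2]
    xs <- x[lo:hi]
    w <- cbs_windows(length(xs), min_bins)
    if (is.null(w)) next
    best <- cbs_max_stat(xs, w)
    if (best$stat <= 0) next
    if (is.infinite(best$stat)) {
      accept <- TRUE
    } else {
      stream <- stream + 1L
      exceed <- with_seed(child_seed(seed, stream), {
        e <- 0L
        for (p in seq_len(n_perm)) {
          if (cbs_max_stat(sample(xs), w)$stat >= best$stat) {
            e <- e + 1L
            if (e > limit) break   # can no longer reach alpha
          }
        }
        e
      })
      accept <- exceed <= limit
    }
    if (accept) {
      nl <- length(xs)
      if (best$i > 0L) cuts <- c(cuts, lo - 1L + best$i)
      if (best$j < nl) cuts <- c(cuts, lo - 1L + best$j)
      if (best$i > 0L) todo <- c(todo, list(c(lo, lo - 1L + best$i)))
      todo <- c(todo, list(c(lo + best$i, lo - 1L + best$j)))
      if (best$j < nl) todo <- c(todo, list(c(lo + best$j, hi)))
    }
  }
  sort(unique(cuts))
}

#' Assign integer copy numbers to segments
#'
#' Copy number per segment is `round(ploidy * 2^mean_log2)` with ties
#' (exact .5) rounded half away from zero, floored at 0. The base ploidy is
#' a per-cell-line preset (the profiles themselves only constrain ratios):
#' e.g. 5 for a ~107-chromosome line, 2 for a ~52-chromosome line.
#'
#' @param segments a `segment_set` from [segment_profile()].
#' @param ploidy integer base ploidy >= 1.
#' @return the `segment_set` with a `cn` column and `ploidy` attribute.
#' @export
call_copy_numbers <- function(segments, ploidy) {
  stopifnot(inherits(segments, "segment_set"))
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("`ploidy` must be an integer >= 1")
  segments$cn <- pmax(0, round_half_away(ploidy * 2^segments$mean_log2))
  attr(segments, "ploidy") <- ploidy
  segments
}
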