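#' Classifier configuration for the baseline-distance comparison
#'
#' The "unchanged" band half-width defaults to twice the dispersion of the
#' MedianRatio-normalised bins, mirroring the convention that a locus is
#' unchanged when the knock-down minus control log2-ratio difference stays
#' within 2 x the profile's ratio dispersion. The dispersion operator is
#' pluggable because the convention does not pin one down; the choice is
#' recorded in the output provenance.
#'
#' @param half_width unchanged-band half-width on the log2 delta scale
#'   (>= 0); computed as `multiplier * dispersion` when omitted.
#' @param dispersion dispersion of the control profile's normalised bins,
#'   from [estimate_dispersion()].
#' @param multiplier band multiplier (default 2).
#' @param estimator name of the dispersion estimator used (bookkeeping).
#' @param sign_flip class given to an exact sign flip (gain in one
#'   condition, equal-magnitude loss in the other, delta outside the band):
#'   `"further"` (default: the knock-down state is a new alteration),
#'   `"closer"` or `"unchanged"`.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(half_width = NULL, dispersion = NULL,
                              multiplier = 2, estimator = "mad",
                              sign_flip = c("further", "closer", "unchanged")) {
  sign_flip <- match.arg(sign_flip)
  if (is.null(half_width)) {
    if (is.null(dispersion))
      stop("supply `half_width` or `dispersion`")
    half_width <- multiplier * dispersion
  }
  if (half_width < 0) stop("`half_width` must be >= 0")
  structure(list(half_width = half_width, multiplier = multiplier,
                 estimator = estimator, sign_flip = sign_flip),
            class = "classifier_config")
}

#' Robust dispersion of normalised bin ratios
#'
#' Estimates the spread of per-bin log2 ratios about their local level:
#' about segment means when a segmentation is supplied (the recommended
#' route — copy-number structure then does not inflate the estimate),
#' otherwise about per-chromosome medians. The default estimator is the
#' median absolute deviation scaled by 1.4826; `"sd"` and `"iqr"`
#' (IQR/1.349) are alternatives. This quantity scales the unchanged band of
#' [classify_loci()].
#'
#' @param profile a `ratio_profile` with >= 50 unmasked bins.
#' @param segments optional `segment_set` on the same profile.
#' @param estimator `"mad"`, `"sd"` or `"iqr"`.
#' @return dispersion (log2 units) with attribute `estimator`.
#' @export
estimate_dispersion <- function(profile, segments = NULL,
                                estimator = c("mad", "sd", "iqr")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(profile, "ratio_profile"))
  ok <- !profile$masked
  if (sum(ok) < 50) stop("dispersion estimation needs >= 50 unmasked bins")
  x <- profile$log2ratio[ok]
  level <- if (!is.null(segments)) {
    stopifnot(inherits(segments, "segment_set"))
    seg_level_for_bins(profile[ok, , drop = FALSE], segments)
  } else {
    stats::ave(x, profile$chrom[ok], FUN = stats::median)
  }
  resid <- x - level
  est <- switch(estimator,
                mad = stats::mad(resid, center = 0),
                sd = stats::sd(resid),
                iqr = stats::IQR(resid) / 1.349)
  structure(est, estimator = estimator)
}

seg_level_for_bins <- function(bins, segments) {
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    b <- bins$chrom == ch
    if (nrow(s) == 0) { out[b] <- stats::median(bins$log2ratio[b]); next }
    mid <- (bins$start[b] + bins$end[b]) / 2
    out[b] <- s$mean_log2[findInterval(mid, s$start)]
  }
  out
}

# Coerce a segment_set / ratio_profile / plain interval table into
# (chrom, start, end, value) with one log2 value per interval.
as_value_intervals <- function(x) {
  if (inherits(x, "ratio_profile")) {
    keep <- !x$masked
    return(data.frame(chrom = x$chrom[keep], start = x$start[keep],
                      end = x$end[keep], value = x$log2ratio[keep]))
  }
  if (inherits(x, "segment_set")) {
    keep <- !is.na(x$mean_log2)
    return(data.frame(chrom = x$chrom[keep], start = x$start[keep],
                      end = x$end[keep], value = x$mean_log2[keep]))
  }
  if (is.data.frame(x) && all(c("chrom", "start", "end") %in% names(x))) {
    vcol <- intersect(c("value", "mean_log2", "log2ratio"), names(x))[1]
    if (is.na(vcol)) stop("no log2 value column found")
    keep <- !is.na(x[[vcol]])
    return(data.frame(chrom = x$chrom[keep], start = x$start[keep],
                      end = x$end[keep], value = x[[vcol]][keep]))
  }
  stop("cannot interpret input as a segment set or ratio profile")
}

#' Pair two profiles on their common loci
#'
#' Intersects the covered intervals of a control and a knock-down profile
#' (segment sets or per-bin ratio profiles) into the finest common tiling
#' and subtracts the locus-matched log2 ratios (knock-down minus control).
#' Loci masked or uncovered in either profile are excluded from both.
#'
#' @param control,knockdown `segment_set`, `ratio_profile`, or interval
#'   data.frames with a log2 value column.
#' @return a `paired_profile`: data.frame `chrom`, `start`, `end`,
#'   `control`, `knockdown`, `delta` (= knockdown - control).
#' @export
pair_profiles <- function(control, knockdown) {
  a <- as_value_intervals(control)
  b <- as_value_intervals(knockdown)
  if (nrow(a) > 0 && nrow(b) > 0 &&
      length(intersect(unique(a$chrom), unique(b$chrom))) == 0)
    stop(sprintf("disjoint chromosome sets: control has {%s}, knockdown has {%s}",
                 paste(unique(a$chrom), collapse = ","),
                 paste(unique(b$chrom), collapse = ",")))
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  pieces <- lapply(chroms, function(ch) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    ai <- ai[order(ai$start), , drop = FALSE]
    bi <- bi[order(bi$start), , drop = FALSE]
    bp <- sort(unique(c(ai$start, ai$end, bi$start, bi$end)))
    if (length(bp) < 2) return(NULL)
    lo <- bp[-length(bp)]; hi <- bp[-1]
    mid <- (lo + hi) / 2
    va <- interval_value_at(ai, mid)
    vb <- interval_value_at(bi, mid)
    keep <- !is.na(va) & !is.na(vb)
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = lo[keep], end = hi[keep],
               control = va[keep], knockdown = vb[keep],
               delta = vb[keep] - va[keep])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), control = numeric(0),
                      knockdown = numeric(0), delta = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("paired_profile", "data.frame"))
}

# value of the interval covering each query point, NA if uncovered
interval_value_at <- function(iv, at) {
  if (nrow(iv) == 0) return(rep(NA_real_, length(at)))
  i <- findInterval(at, iv$start)
  v <- ifelse(i >= 1 & at < iv$end[pmax(i, 1)], iv$value[pmax(i, 1)], NA_real_)
  v
}

#' Classify loci as closer to / further from the zero-baseline
#'
#' Distance from baseline at a locus is the magnitude of its log2 ratio,
#' `d(x) = |log2 ratio|`. A locus is `unchanged` when
#' `|delta| <= half_width`; otherwise it is `further` when the knock-down
#' sits further from the baseline than the control (`d(kd) > d(ctrl)`:
#' knock-down gain exceeds control gain, or knock-down loss exceeds control
#' loss) and `closer` when `d(kd) < d(ctrl)`. The exact tie
#' `d(kd) == d(ctrl)` with `|delta| > half_width` — a pure sign flip — takes
#' the configured `sign_flip` class.
#'
#' @param paired a [pair_profiles()] result.
#' @param config a [classifier_config()].
#' @return a `delta_classification`: the paired table plus a `class` factor
#'   (`closer`/`further`/`unchanged`), with attribute `config`.
#' @export
classify_loci <- function(paired, config) {
  stopifnot(inherits(paired, "paired_profile"),
            inherits(config, "classifier_config"))
  d_c <- abs(paired$control)
  d_k <- abs(paired$knockdown)
  cls <- ifelse(abs(paired$delta) <= config$half_width, "unchanged",
         ifelse(d_k > d_c, "further",
         ifelse(d_k < d_c, "closer", config$sign_flip)))
  out <- paired
  out$class <- factor(cls, levels = c("closer", "further", "unchanged"))
  structure(out, config = config,
            class = c("delta_classification", class(paired)))
}

#' Summarise a baseline-distance classification
#'
#' Totals the classified genome in Mbp per class and expresses closer and
#' further as percentages of the *changed* loci only (so the two
#' percentages sum to 100 whenever any locus changed; with no changed loci
#' they are `NA`). Also tabulates changed Mbp per chromosome.
#'
#' @param classification a [classify_loci()] result.
#' @return a `baseline_summary` list: `mbp` (named closer/further/unchanged),
#'   `pct` (closer/further over changed loci), `compared_mbp`,
#'   `per_chromosome` (data.frame `chrom`, `changed_mbp`, `compared_mbp`,
#'   `changed_fraction`), and the classifier `config`.
#' @export
summarize_baseline_distance <- function(classification) {
  stopifnot(inherits(classification, "delta_classification"))
  bp <- classification$end - classification$start
  tot <- vapply(c("closer", "further", "unchanged"), function(k)
    sum(bp[classification$class == k]), numeric(1))
  changed <- tot[["closer"]] + tot[["further"]]
  pct <- if (changed > 0)
    c(closer = 100 * tot[["closer"]] / changed,
      further = 100 * tot[["further"]] / changed)
  else c(closer = NA_real_, further = NA_real_)
  per_chr <- do.call(rbind, lapply(unique(classification$chrom), function(ch) {
    i <- classification$chrom == ch
    cmp <- sum(bp[i])
    chg <- sum(bp[i & classification$class != "unchanged"])
    data.frame(chrom = ch, changed_mbp = chg / 1e6, compared_mbp = cmp / 1e6,
               changed_fraction = if (cmp > 0) chg / cmp else 0)
  }))
  structure(list(mbp = tot / 1e6, pct = pct,
                 compared_mbp = sum(bp) / 1e6,
                 per_chromosome = per_chr,
                 config = attr(classification, "config")),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("baseline-distance summary\n")
  if (is.na(x$pct[["closer"]])) {
    cat(sprintf("  no changed loci (unchanged: %.1f Mbp of %.1f Mbp compared)\n",
                x$mbp[["unchanged"]], x$compared_mbp))
  } else {
    cat(sprintf("  closer to baseline : %.1f%% (%.1f Mbp)\n",
                x$pct[["closer"]], x$mbp[["closer"]]))
    cat(sprintf("  further from baseline: %.1f%% (%.1f Mbp)\n",
                x$pct[["further"]], x$mbp[["further"]]))
    cat(sprintf("  unchanged: %.1f Mbp of %.1f Mbp compared\n",
                x$mbp[["unchanged"]], x$compared_mbp))
  }
  invisible(x)
}

#' Chromosomes affected by the knock-down
#'
#' Chromosomes whose changed (closer + further) fraction of compared bp
#' meets a threshold, ordered by changed Mbp descending. The threshold is a
#' parameter: the underlying "affected" criterion is a reporting convention,
#' not a measurement.
#'
#' @param classification a [classify_loci()] result.
#' @param min_changed_fraction threshold in (0, 1].
#' @return character vector of chromosome names.
#' @export
affected_chromosomes <- function(classification, min_changed_fraction = 0.1) {
  if (min_changed_fraction <= 0 || min_changed_fraction > 1)
    stop("`min_changed_fraction` must be in (0, 1]")
  s <- summarize_baseline_distance(classification)$per_chromosome
  s <- s[s$changed_fraction >= min_changed_fraction, , drop = FALSE]
  s$chrom[order(-s$changed_mbp)]
}
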