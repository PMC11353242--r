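# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written with naive/direct algorithms, separate
# from the package implementations they check.

# A ratio_profile with prescribed per-bin log2 values (single or multiple
# chromosomes), bypassing the count layer for tests that exercise
# segmentation/classification in isolation.
make_ratio_profile <- function(log2, chrom = "chr1", bin = 1e6) {
  chrom <- rep_len(chrom, length(log2))
  idx <- stats::ave(seq_along(log2), chrom, FUN = seq_along)
  df <- data.frame(chrom = chrom,
                   start = (idx - 1) * bin, end = idx * bin,
                   gc = 0.45, count = 100 * 2^log2,
                   ratio = 2^log2, log2ratio = log2, masked = FALSE)
  attr(df, "median_ratio") <- 100
  class(df) <- c("ratio_profile", "bin_track", "data.frame")
  df
}

make_segment_set <- function(df) {
  structure(df, class = c("segment_set", "data.frame"))
}

# Random paired profile for property tests: random locus widths and
# independent Gaussian log2 levels in both conditions.
random_paired_profile <- function(n_loci, seed) {
  set.seed(seed)
  w <- sample(1:20, n_loci, replace = TRUE) * 1e6
  s <- cumsum(c(0, w[-n_loci]))
  ctrl <- stats::rnorm(n_loci, 0, 0.8)
  kd <- stats::rnorm(n_loci, 0, 0.8)
  structure(data.frame(chrom = "chr1", start = s, end = s + w,
                       control = ctrl, knockdown = kd, delta = kd - ctrl),
            class = c("paired_profile", "data.frame"))
}

swap_paired <- function(p) {
  out <- p
  out$control <- p$knockdown
  out$knockdown <- p$control
  out$delta <- -p$delta
  out
}

# Independent truth-table evaluator for the closer/further/unchanged rule,
# written as literal case analysis (no reuse of package code).
oracle_classify <- function(ctrl, kd, hw, sign_flip = "further") {
  mapply(function(c0, k0) {
    if (abs(k0 - c0) <= hw) return("unchanged")
    dc <- abs(c0); dk <- abs(k0)
    if (dk > dc) return("further")
    if (dk < dc) return("closer")
    sign_flip
  }, ctrl, kd)
}

# Exhaustive window scan: best contiguous window (i, j] by two-sample t
# statistic (window vs rest), computed naively with mean()/var() per
# candidate. Flank constraints mirror the segmentation contract: every
# non-empty piece keeps >= min_bins bins.
oracle_best_window <- function(x, min_bins) {
  n <- length(x)
  best_t <- -Inf; best <- NULL
  for (i in 0:(n - min_bins)) {
    if (i != 0 && i < min_bins) next
    for (j in (i + min_bins):n) {
      if (j != n && j > n - min_bins) next
      if (i == 0 && j == n) next
      a <- x[(i + 1):j]; b <- x[-((i + 1):j)]
      k <- length(a)
      sp2 <- ((k - 1) * stats::var(a) + (n - k - 1) * stats::var(b)) /
        (n - 2) * (1 / k + 1 / (n - k))
      tt <- if (sp2 > 0) (mean(a) - mean(b))^2 / sp2
            else if (mean(a) != mean(b)) Inf else 0
      if (tt > best_t) { best_t <- tt; best <- list(i = i, j = j) }
    }
  }
  cuts <- c(if (best$i > 0) best$i, if (best$j < n) best$j)
  list(stat = best_t, i = best$i, j = best$j, cuts = cuts)
}

# Exhaustive minimum of the frame-linking objective: sum of squared link
# displacements plus cap^2 per unlinked spot on either side, over all
# partial matchings of p1 (n1 x 2) to p2 (n2 x 2). Links longer than cap
# are forbidden.
oracle_min_link_cost <- function(p1, p2, cap) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  cap2 <- cap^2
  d2 <- outer(seq_len(n1), seq_len(n2), function(i, j)
    (p1[i, 1] - p2[j, 1])^2 + (p1[i, 2] - p2[j, 2])^2)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) {
      total <- cost + cap2 * sum(!used)
      if (total < best) best <<- total
      return()
    }
    rec(i + 1L, used, cost + cap2)      # leave spot i unlinked
    for (j in which(!used)) {
      if (d2[i, j] <= cap2) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, n2), 0)
  best
}

# Achieved linking cost of a track_set between two consecutive frames,
# under the same objective as oracle_min_link_cost.
achieved_link_cost <- function(tracks, f1, f2, cap) {
  cap2 <- cap^2
  a <- tracks[tracks$frame == f1, ]
  b <- tracks[tracks$frame == f2, ]
  linked <- intersect(a$track, b$track)
  cost <- 0
  for (tr in linked) {
    pa <- a[a$track == tr, ]; pb <- b[b$track == tr, ]
    cost <- cost + (pa$x - pb$x)^2 + (pa$y - pb$y)^2
  }
  cost + cap2 * (nrow(a) - length(linked)) + cap2 * (nrow(b) - length(linked))
}

# Full enumeration of the Mann-Whitney null: distribution of U over all
# ways to place sample a's values among the pooled order statistics.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pos <- utils::combn(n1 + n2, n1)
  us <- apply(pos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Gaussian blob image used in detection tests.
blob_image <- function(h, w, cx, cy, sigma = 2, amp = 100, bg = 0) {
  xs <- seq_len(w); ys <- seq_len(h)
  bg + amp * exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * sigma^2))
}
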