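#' Parameters for the binned read-depth simulator
#'
#' @param mean_count expected reads per bin at copy-neutral state (> 0).
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2). `0` is the exact-expectation mode: bins carry their expected
#'   value with no sampling.
#' @param gc_linear,gc_quadratic coefficients of the multiplicative GC-bias
#'   factor `1 + gc_linear*(gc - 0.45) + gc_quadratic*(gc - 0.45)^2`.
#' @param seed RNG seed for the count draws.
#' @return object of class `read_depth_params`.
#' @export
read_depth_params <- function(mean_count = 100, dispersion = 0.05,
                              gc_linear = 0, gc_quadratic = 0, seed = 1L) {
  if (mean_count <= 0) stop("`mean_count` must be > 0")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  structure(list(mean_count = mean_count, dispersion = dispersion,
                 gc_linear = gc_linear, gc_quadratic = gc_quadratic,
                 seed = seed),
            class = "read_depth_params")
}

new_cn_profile <- function(df, condition) {
  rownames(df) <- NULL
  structure(df, condition = condition,
            class = c("cn_profile", "data.frame"))
}

#' Simulate paired control / knock-down copy-number ground truth
#'
#' Builds two integer copy-number profiles on the same genome. The control
#' carries `n_alterations` non-neutral segments of `alteration_length` bp (default 20 Mbp: arm-scale events on the 720 Mbp toy genome)
#' placed on a non-overlapping slot grid; each alteration doubles or halves
#' the local copy number relative to base ploidy with equal probability
#' (two-copy gain CN4 or single-copy loss CN1 at diploid base), giving
#' symmetric log2 effects of +-1 that stay visible above shallow-coverage
#' read noise and never zero out the read signal. The knock-down starts as
#' a copy of the control, then (i) a fraction `attenuation_fraction` of the
#' altered bp reverts to base ploidy (these loci are "closer-eligible": the
#' knock-down is nearer the baseline than the control), and (ii) novel
#' alterations amounting to `new_alteration_fraction` of the altered bp are
#' added at previously neutral loci ("further-eligible").
#'
#' @param genome a [genome_model()].
#' @param n_alterations number of control alterations (>= 0).
#' @param alteration_length length of each alteration in bp; a multiple of
#'   the genome bin size keeps alterations bin-aligned.
#' @param attenuation_fraction fraction in \[0,1\] of altered bp attenuated
#'   in the knock-down.
#' @param new_alteration_fraction fraction in \[0,1\] of altered bp added as
#'   novel knock-down alterations.
#' @param seed RNG seed.
#' @return list of class `cn_simulation` with elements `control` and
#'   `knockdown` (class `cn_profile`: data.frames of `chrom`, `start`,
#'   `end`, `cn` tiling the genome) and `truth`, a list with ground-truth
#'   `closer_bp`, `further_bp`, `altered_bp` and the altered/attenuated/new
#'   interval tables.
#' @export
simulate_cn_profiles <- function(genome, n_alterations = 10,
                                 alteration_length = 20e6,
                                 attenuation_fraction = 0.7,
                                 new_alteration_fraction = 0.3,
                                 seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  stopifnot_scalar_fraction(attenuation_fraction, "attenuation_fraction")
  stopifnot_scalar_fraction(new_alteration_fraction, "new_alteration_fraction")
  if (n_alterations < 0) stop("`n_alterations` must be >= 0")

  # candidate slots: non-overlapping tiles of alteration_length per chromosome
  slots <- do.call(rbind, lapply(genome$chrom, function(ch) {
    k <- floor(genome$length[[ch]] / alteration_length)
    if (k < 1) return(NULL)
    data.frame(chrom = ch,
               start = alteration_length * (seq_len(k) - 1),
               end = alteration_length * seq_len(k),
               stringsAsFactors = FALSE)
  }))
  capacity <- if (is.null(slots)) 0L else nrow(slots)
  n_atten <- round(attenuation_fraction * n_alterations)
  n_new <- round(new_alteration_fraction * n_alterations)
  if (n_alterations + n_new > capacity)
    stop(sprintf(paste0("requested %d control + %d novel alterations of ",
                        "%.3g bp exceed genome capacity of %d slots"),
                 n_alterations, n_new, alteration_length, capacity))

  cn_gain <- 2L * genome$ploidy
  cn_loss <- max(1L, genome$ploidy %/% 2L)
  drawn <- with_seed(seed, {
    idx <- sample.int(capacity, n_alterations + n_new)
    ctrl_idx <- idx[seq_len(n_alterations)]
    new_idx <- idx[n_alterations + seq_len(n_new)]
    cn <- sample(c(cn_gain, cn_loss), n_alterations + n_new, replace = TRUE)
    atten_pick <- if (n_alterations > 0)
      sort(sample.int(n_alterations, n_atten)) else integer(0)
    list(ctrl_idx = ctrl_idx, new_idx = new_idx, cn = cn,
         atten_pick = atten_pick)
  })

  ctrl_alt <- if (n_alterations > 0) slots[drawn$ctrl_idx, , drop = FALSE]
              else slots[0, , drop = FALSE]
  ctrl_alt$cn <- drawn$cn[seq_len(n_alterations)]
  new_alt <- if (n_new > 0) slots[drawn$new_idx, , drop = FALSE]
             else slots[0, , drop = FALSE]
  new_alt$cn <- drawn$cn[n_alterations + seq_len(n_new)]

  kd_alt <- ctrl_alt
  kd_alt$cn[drawn$atten_pick] <- genome$ploidy  # alteration lost in knock-down
  kd_alt <- rbind(kd_alt, new_alt)

  control <- new_cn_profile(overlay_alterations(genome, ctrl_alt), "control")
  knockdown <- new_cn_profile(overlay_alterations(genome, kd_alt), "knockdown")

  atten_tab <- ctrl_alt[drawn$atten_pick, , drop = FALSE]
  truth <- list(
    closer_bp = sum(atten_tab$end - atten_tab$start),
    further_bp = sum(new_alt$end - new_alt$start),
    altered_bp = sum(ctrl_alt$end - ctrl_alt$start),
    control_alterations = ctrl_alt,
    attenuated = atten_tab,
    novel = new_alt)
  structure(list(control = control, knockdown = knockdown, truth = truth),
            class = "cn_simulation")
}

# Lay alteration intervals (chrom,start,end,cn) over a neutral genome,
# returning a sorted segment table that tiles each chromosome exactly.
overlay_alterations <- function(genome, alt) {
  segs <- lapply(genome$chrom, function(ch) {
    len <- genome$length[[ch]]
    a <- alt[alt$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    bp <- sort(unique(c(0, len, a$start, a$end)))
    start <- bp[-length(bp)]
    end <- bp[-1]
    cn <- rep.int(genome$ploidy, length(start))
    if (nrow(a) > 0) {
      for (i in seq_len(nrow(a))) {
        hit <- start >= a$start[i] & end <= a$end[i]
        cn[hit] <- a$cn[i]
      }
    }
    # merge adjacent runs of equal copy number
    keep <- c(TRUE, cn[-1] != cn[-length(cn)])
    grp <- cumsum(keep)
    data.frame(chrom = ch,
               start = tapply(start, grp, min),
               end = tapply(end, grp, max),
               cn = cn[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

# Smooth deterministic GC track in [0.3, 0.6]: a slow sinusoid along the
# concatenated genome. Deterministic on purpose so GC is a property of the
# genome, not of the read-depth draw.
synthesize_gc <- function(n_bins) {
  0.45 + 0.15 * sin(2 * pi * seq_len(n_bins) / 97)
}

#' Simulate binned read counts from a copy-number profile
#'
#' Expected count per bin is `mean_count * (cn / ploidy) * gc_factor(gc)`;
#' counts are drawn from a negative binomial with the stated dispersion
#' (`dispersion = 0` returns the expectation exactly). GC per bin is a
#' smooth deterministic track in \[0.3, 0.6\].
#'
#' @param profile a `cn_profile` tiling `genome`.
#' @param genome the [genome_model()] the profile lives on.
#' @param params a [read_depth_params()].
#' @return a `bin_track`: data.frame with `chrom`, `start`, `end`, `gc`,
#'   `count`.
#' @export
simulate_bin_counts <- function(profile, genome, params = read_depth_params()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(params, "read_depth_params"))
  bins <- genome_bins(genome)
  bins$gc <- synthesize_gc(nrow(bins))
  cn <- lookup_cn(profile, bins)
  gcf <- pmax(0, 1 + params$gc_linear * (bins$gc - 0.45) +
                params$gc_quadratic * (bins$gc - 0.45)^2)
  mu <- params$mean_count * (cn / genome$ploidy) * gcf
  bins$count <- if (params$dispersion == 0) mu else
    with_seed(params$seed,
              ifelse(mu == 0, 0,
                     stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / params$dispersion)))
  structure(bins, class = c("bin_track", "data.frame"))
}

# integer copy number of the segment containing each bin midpoint
lookup_cn <- function(profile, bins) {
  cn <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0)
      stop(sprintf("profile does not cover chromosome %s", ch))
    b <- bins$chrom == ch
    mid <- (bins$start[b] + bins$end[b]) / 2
    i <- findInterval(mid, p$start)
    cn[b] <- p$cn[i]
  }
  cn
}
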