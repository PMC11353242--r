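#' Simulate per-cell chromosome counts under missegregation
#'
#' Each cell starts at `base_count` chromosomes and goes through `divisions`
#' divisions; in every division each chromosome independently missegregates
#' with probability `rate`, and a missegregation adds or removes one copy
#' with equal probability. The mean therefore stays at the base count while
#' the cell-to-cell variance grows with the rate — the karyotype-diversity
#' readout of chromosomal instability. Presets of 107 and 52 chromosomes
#' correspond to a highly aneuploid and a near-diploid ovarian carcinoma
#' line.
#'
#' @param n_cells number of cells.
#' @param base_count starting chromosome count (e.g. 107 or 52).
#' @param rate per-division, per-chromosome missegregation probability in
#'   \[0,1\]; `0` yields zero variance.
#' @param divisions number of divisions simulated (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns `cell`, `count`.
#' @export
simulate_karyotypes <- function(n_cells = 100, base_count = 107,
                                rate = 0.01, divisions = 10, seed = 1L) {
  stopifnot(n_cells >= 0, base_count >= 0, divisions >= 0)
  stopifnot_scalar_fraction(rate, "rate")
  counts <- with_seed(seed, {
    vapply(seq_len(n_cells), function(i) {
      n <- base_count
      for (d in seq_len(divisions)) {
        if (rate == 0 || n == 0) next
        k <- stats::rbinom(1L, n, rate)
        if (k > 0) n <- max(0L, n + sum(sample(c(-1L, 1L), k, replace = TRUE)))
      }
      as.integer(n)
    }, integer(1))
  })
  data.frame(cell = seq_len(n_cells), count = counts)
}

#' Simulate a binomial event count
#'
#' Emulates scoring a fixed number of cells for a binary phenotype
#' (micronucleus present, chromosomes aligned, anaphase defective).
#'
#' @param p_event per-cell event probability in \[0,1\].
#' @param n_cells number of cells scored.
#' @param seed RNG seed.
#' @return list with `events` and `n_cells`.
#' @export
simulate_event_counts <- function(p_event, n_cells, seed = 1L) {
  stopifnot_scalar_fraction(p_event, "p_event")
  stopifnot(n_cells >= 0)
  events <- with_seed(seed, stats::rbinom(1L, n_cells, p_event))
  list(events = as.integer(events), n_cells = as.integer(n_cells))
}
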