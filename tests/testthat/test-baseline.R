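test_that("pair_profiles intersects grids into the finest common tiling", {
  # identical grids pair everywhere
  a <- make_segment_set(data.frame(chrom = "chr1", start = c(0, 10e6),
                                   end = c(10e6, 30e6), mean_log2 = c(0.5, 0)))
  p <- pair_profiles(a, a)
  expect_equal(nrow(p), 2L)
  expect_true(all(p$delta == 0))
  # one coarse vs one fine: {[0,30)} x {[0,10),[10,30)} -> {[0,10),[10,30)}
  coarse <- make_segment_set(data.frame(chrom = "chr1", start = 0, end = 30e6,
                                        mean_log2 = 1))
  fine <- make_segment_set(data.frame(chrom = "chr1", start = c(0, 10e6),
                                      end = c(10e6, 30e6),
                                      mean_log2 = c(0.2, 0.8)))
  pp <- pair_profiles(coarse, fine)
  expect_equal(pp$start, c(0, 10e6))
  expect_equal(pp$end, c(10e6, 30e6))
  expect_equal(pp$control, c(1, 1))
  expect_equal(pp$knockdown, c(0.2, 0.8))
  expect_equal(pp$delta, c(-0.8, -0.2))
  # empty input: empty result, no error
  empty <- make_segment_set(data.frame(chrom = character(0),
                                       start = numeric(0), end = numeric(0),
                                       mean_log2 = numeric(0)))
  expect_equal(nrow(pair_profiles(empty, fine)), 0L)
  # disjoint chromosome sets error and name the mismatch
  b <- make_segment_set(data.frame(chrom = "chr9", start = 0, end = 10e6,
                                   mean_log2 = 0))
  expect_error(pair_profiles(a, b), "disjoint.*chr1.*chr9")
})

test_that("pair_profiles excludes loci masked in either profile", {
  ctrl <- make_ratio_profile(c(0, 0.5, 0, 0))
  kd <- make_ratio_profile(c(0, 0, 0, 0.3))
  kd$masked[2] <- TRUE; kd$log2ratio[2] <- NA_real_
  p <- pair_profiles(ctrl, kd)
  expect_equal(nrow(p), 3L)
  expect_false(any(p$start == 1e6))
})

test_that("classification follows the direction rules of the delta track", {
  cfg <- classifier_config(half_width = 0.1)
  # the worked example: control at +1 (e.g. CN4 at baseline CN2 scale),
  # knock-down back at baseline -> closer; mirrored case -> further
  p <- structure(data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                            control = c(1, 0), knockdown = c(0, -0.8),
                            delta = c(-1, -0.8)),
                 class = c("paired_profile", "data.frame"))
  cls <- classify_loci(p, cfg)
  expect_equal(as.character(cls$class), c("closer", "further"))
  # delta = 0 everywhere is all unchanged
  p0 <- structure(data.frame(chrom = "chr1", start = 0, end = 1e6,
                             control = 0.7, knockdown = 0.7, delta = 0),
                  class = c("paired_profile", "data.frame"))
  expect_equal(as.character(classify_loci(p0, cfg)$class), "unchanged")
  # sign flip policy decides the exact-tie cell
  pf <- structure(data.frame(chrom = "chr1", start = 0, end = 1e6,
                             control = 0.5, knockdown = -0.5, delta = -1),
                  class = c("paired_profile", "data.frame"))
  expect_equal(as.character(classify_loci(pf, cfg)$class), "further")
  cfg_c <- classifier_config(half_width = 0.1, sign_flip = "closer")
  expect_equal(as.character(classify_loci(pf, cfg_c)$class), "closer")
})

test_that("classifier agrees with the brute-force truth table on a grid", {
  vals <- seq(-2, 2, by = 0.1)
  grid <- expand.grid(control = vals, knockdown = vals)
  n <- nrow(grid)
  p <- structure(data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1e6,
                            end = seq_len(n) * 1e6, control = grid$control,
                            knockdown = grid$knockdown,
                            delta = grid$knockdown - grid$control),
                 class = c("paired_profile", "data.frame"))
  for (hw in c(0.05, 0.2, 0.5)) {
    got <- as.character(classify_loci(p, classifier_config(half_width = hw))$class)
    want <- oracle_classify(grid$control, grid$knockdown, hw)
    expect_identical(got, unname(want))
  }
})

test_that("dispersion estimation is zero for noise-free profiles and
           recovers Gaussian noise", {
  x <- rep(c(0, 1, -0.5), each = 60)
  p <- make_ratio_profile(x, chrom = rep(c("chr1", "chr2", "chr3"), each = 60))
  segs <- make_segment_set(data.frame(
    chrom = c("chr1", "chr2", "chr3"), start = 0, end = 60e6,
    mean_log2 = c(0, 1, -0.5)))
  expect_equal(as.numeric(estimate_dispersion(p, segs)), 0)
  # Gaussian sd 0.1 about segment means, 3000 bins: within 15%
  set.seed(99)
  y <- rep(0, 3000) + stats::rnorm(3000, 0, 0.1)
  py <- make_ratio_profile(y, chrom = rep(paste0("chr", 1:3), each = 1000))
  segy <- make_segment_set(data.frame(chrom = paste0("chr", 1:3), start = 0,
                                      end = 1000e6, mean_log2 = 0))
  for (est in c("mad", "sd", "iqr")) {
    d <- estimate_dispersion(py, segy, est)
    expect_lt(abs(as.numeric(d) - 0.1) / 0.1, 0.15)
    expect_equal(attr(d, "estimator"), est)
  }
})

test_that("summaries report Mbp and percentages over changed loci", {
  cfg <- classifier_config(half_width = 0.1)
  p <- structure(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 30e6, 0), end = c(30e6, 40e6, 50e6),
    control = c(1, 0, 0.2), knockdown = c(0, 1, 0.2),
    delta = c(-1, 1, 0)),
    class = c("paired_profile", "data.frame"))
  s <- summarize_baseline_distance(classify_loci(p, cfg))
  expect_equal(unname(s$mbp), c(30, 10, 50))
  expect_equal(unname(s$pct), c(75, 25))
  expect_equal(sum(s$mbp), s$compared_mbp)   # conservation
  # all unchanged: percentages are NA, not 0/0
  p0 <- structure(data.frame(chrom = "chr1", start = 0, end = 10e6,
                             control = 0, knockdown = 0, delta = 0),
                  class = c("paired_profile", "data.frame"))
  s0 <- summarize_baseline_distance(classify_loci(p0, cfg))
  expect_true(all(is.na(s0$pct)))
  expect_equal(unname(s0$mbp[["unchanged"]]), 10)
})

test_that("affected chromosomes honour the changed-fraction threshold", {
  cfg <- classifier_config(half_width = 0.1)
  # chr1 40% changed, chr2 5% changed
  p <- structure(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0, 40e6, 0, 5e6), end = c(40e6, 100e6, 5e6, 100e6),
    control = c(1, 0, 1, 0), knockdown = c(0, 0, 0, 0),
    delta = c(-1, 0, -1, 0)),
    class = c("paired_profile", "data.frame"))
  cls <- classify_loci(p, cfg)
  expect_equal(affected_chromosomes(cls, 0.1), "chr1")
  expect_equal(affected_chromosomes(cls, 0.01), c("chr1", "chr2"))
  # all unchanged: empty list
  cls0 <- classify_loci(swap_paired(swap_paired(p)), cfg)
  cls0$class[] <- "unchanged"
  expect_length(affected_chromosomes(cls0, 0.1), 0L)
})

test_that("classification is antisymmetric under condition swap", {
  cfg <- classifier_config(half_width = 0.15)
  for (s in 1:20) {
    p <- random_paired_profile(40, seed = s)
    a <- classify_loci(p, cfg)
    b <- classify_loci(swap_paired(p), cfg)
    map <- c(closer = "further", further = "closer", unchanged = "unchanged")
    expect_identical(as.character(b$class),
                     unname(map[as.character(a$class)]))
  }
})

test_that("widening the unchanged band never shrinks unchanged bp", {
  p <- random_paired_profile(60, seed = 123)
  widths <- c(0, 0.05, 0.1, 0.3, 0.6, 1.2)
  unchanged_bp <- vapply(widths, function(hw) {
    cls <- classify_loci(p, classifier_config(half_width = hw))
    sum((cls$end - cls$start)[cls$class == "unchanged"])
  }, numeric(1))
  expect_true(all(diff(unchanged_bp) >= 0))
})
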