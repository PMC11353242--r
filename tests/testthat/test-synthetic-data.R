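test_that("toy genome totals 720 Mbp with 22 bin-aligned autosomes", {
  g <- toy_genome()
  expect_length(g$chrom, 22L)
  expect_equal(sum(g$length), 720e6)
  bins <- genome_bins(g)
  expect_equal(sum(bins$end - bins$start), 720e6)
  expect_equal(nrow(bins), 720L)
})

test_that("cn profile simulation: identity, determinism, conservation", {
  g <- toy_genome()
  # attenuation 0 / new 0: knockdown identical to control
  sim0 <- simulate_cn_profiles(g, 10, 20e6, 0, 0, seed = 5)
  strip <- function(p) {
    df <- as.data.frame(p)
    attr(df, "condition") <- NULL
    df
  }
  expect_identical(strip(sim0$control), strip(sim0$knockdown))
  expect_equal(sim0$truth$closer_bp, 0)
  expect_equal(sim0$truth$further_bp, 0)
  # fixed seed reproduces byte-identically
  sim_a <- simulate_cn_profiles(g, seed = 7)
  sim_b <- simulate_cn_profiles(g, seed = 7)
  expect_identical(sim_a, sim_b)
  # segments tile the genome exactly, every seed
  for (s in 1:5) {
    sim <- simulate_cn_profiles(g, seed = s)
    for (prof in list(sim$control, sim$knockdown)) {
      expect_equal(sum(prof$end - prof$start), sum(g$length))
      for (ch in g$chrom) {
        p <- prof[prof$chrom == ch, ]
        expect_equal(p$start[1], 0)
        expect_equal(p$end[nrow(p)], unname(g$length[ch]))
        if (nrow(p) > 1) expect_equal(p$start[-1], p$end[-nrow(p)])
      }
    }
  }
})

test_that("cn profile ground truth matches interval-arithmetic recomputation", {
  g <- toy_genome()
  for (s in c(3, 11, 29)) {
    sim <- simulate_cn_profiles(g, 10, 10e6, 0.7, 0.3, seed = s)
    expect_equal(sim$truth$altered_bp, 100e6)
    expect_equal(sim$truth$closer_bp, 70e6)
    expect_equal(sim$truth$further_bp, 30e6)
    # independent sweep: compare copy-number distance from ploidy per
    # elementary interval of the union of breakpoints
    closer <- further <- 0
    for (ch in g$chrom) {
      ctrl <- sim$control[sim$control$chrom == ch, ]
      kd <- sim$knockdown[sim$knockdown$chrom == ch, ]
      bp <- sort(unique(c(ctrl$start, ctrl$end, kd$start, kd$end)))
      for (i in seq_len(length(bp) - 1)) {
        mid <- (bp[i] + bp[i + 1]) / 2
        c_cn <- ctrl$cn[findInterval(mid, ctrl$start)]
        k_cn <- kd$cn[findInterval(mid, kd$start)]
        dc <- abs(c_cn - g$ploidy); dk <- abs(k_cn - g$ploidy)
        w <- bp[i + 1] - bp[i]
        if (dk < dc) closer <- closer + w
        if (dk > dc) further <- further + w
      }
    }
    expect_identical(closer, sim$truth$closer_bp)
    expect_identical(further, sim$truth$further_bp)
  }
})

test_that("cn profile simulation errors when capacity is exceeded", {
  g <- genome_model("chr1", 50e6, bin_size = 1e6)
  expect_error(simulate_cn_profiles(g, 10, 10e6, 0.5, 0.5, seed = 1),
               "capacity of 5 slots")
})

test_that("bin counts: expectation mode is exact and linear in copy number", {
  g <- toy_genome()
  neutral <- simulate_cn_profiles(g, 0, 20e6, 0, 0, seed = 1)$control
  tr <- simulate_bin_counts(neutral, g, read_depth_params(100, 0))
  expect_true(all(tr$count == 100))
  expect_true(all(tr$gc >= 0.3 & tr$gc <= 0.6))
  # doubled copy number on one chromosome doubles the expectation
  prof <- as.data.frame(neutral)
  prof$cn[prof$chrom == "chr5"] <- 2L * g$ploidy
  tr2 <- simulate_bin_counts(structure(prof, class = class(neutral)), g,
                             read_depth_params(100, 0))
  expect_true(all(tr2$count[tr2$chrom == "chr5"] == 200))
  expect_true(all(tr2$count[tr2$chrom != "chr5"] == 100))
})

test_that("bin counts at dispersion 0.1 recover the expectation to 3%", {
  g <- toy_genome(bin_size = 240e3)   # 3000 bins
  neutral <- simulate_cn_profiles(g, 0, 20e6, 0, 0, seed = 1)$control
  tr <- simulate_bin_counts(neutral, g, read_depth_params(100, 0.1, seed = 9))
  # 3000 full bins plus per-chromosome remainder bins
  expect_equal(nrow(tr), nrow(genome_bins(g)))
  expect_gte(nrow(tr), 3000L)
  expect_lt(abs(mean(tr$count) - 100) / 100, 0.03)
})

test_that("bin count draws are seed-deterministic", {
  g <- toy_genome()
  sim <- simulate_cn_profiles(g, seed = 2)
  a <- simulate_bin_counts(sim$control, g, read_depth_params(100, 0.05, seed = 4))
  b <- simulate_bin_counts(sim$control, g, read_depth_params(100, 0.05, seed = 4))
  expect_identical(a, b)
})

test_that("karyotype simulator: zero rate, mean recovery, variance growth", {
  k0 <- simulate_karyotypes(50, 107, rate = 0, divisions = 10, seed = 1)
  expect_true(all(k0$count == 107))
  expect_equal(stats::var(k0$count), 0)
  k <- simulate_karyotypes(500, 107, rate = 0.01, divisions = 10, seed = 2)
  expect_lt(abs(mean(k$count) - 107) / 107, 0.02)
  v_lo <- stats::var(simulate_karyotypes(500, 107, 0.01, 10, seed = 3)$count)
  v_hi <- stats::var(simulate_karyotypes(500, 107, 0.05, 10, seed = 3)$count)
  expect_lt(v_lo, v_hi)
})

test_that("event counts are binomial draws with degenerate endpoints", {
  expect_equal(simulate_event_counts(0, 100, seed = 1)$events, 0L)
  expect_equal(simulate_event_counts(1, 100, seed = 1)$events, 100L)
  ev <- simulate_event_counts(0.2, 1000, seed = 5)
  # closed-form binomial 99% interval
  band <- stats::qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(ev$events, band[1])
  expect_lte(ev$events, band[2])
})

test_that("comet movie: geometry, unit conversion and determinism", {
  # stationary emitter: identical centroid in all frames
  s0 <- simulate_comet_movie(n_frames = 10, n_emitters = 1, speed = 0,
                             width = 64, height = 64, noise_sd = 0, seed = 3)
  expect_equal(length(unique(s0$truth$x)), 1L)
  expect_equal(length(unique(s0$truth$y)), 1L)
  # 3 um/min at 0.1 um/px and 2 s/frame is exactly 1 px/frame
  s1 <- simulate_comet_movie(n_frames = 5, interval = 2, pixel_size = 0.1,
                             n_emitters = 1, speed = 3, width = 64,
                             height = 64, noise_sd = 0, seed = 4)
  disp <- sqrt(diff(s1$truth$x)^2 + diff(s1$truth$y)^2)
  expect_equal(disp, rep(1.0, 4))
  # noise-free peak: amplitude above background at the rounded centroid
  s2 <- simulate_comet_movie(n_frames = 1, n_emitters = 1, speed = 0,
                             heading = 0, width = 64, height = 64,
                             amplitude = 50, background = 0, noise_sd = 0,
                             psf_sigma = 1.5, seed = 8)
  f <- matrix(s2$movie$frames[1, , ], 64, 64)
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_equal(peak[1, "col"], round(s2$truth$x[1]), ignore_attr = TRUE,
               tolerance = 1)
  expect_equal(peak[1, "row"], round(s2$truth$y[1]), ignore_attr = TRUE,
               tolerance = 1)
  expect_lte(max(f), 50)
  # determinism
  a <- simulate_comet_movie(n_frames = 3, n_emitters = 2, width = 64,
                            height = 64, seed = 11)
  b <- simulate_comet_movie(n_frames = 3, n_emitters = 2, width = 64,
                            height = 64, seed = 11)
  expect_identical(a, b)
  # emitters that cannot fit are refused
  expect_error(simulate_comet_movie(n_frames = 90, n_emitters = 1,
                                    speed = 30, width = 32, height = 32),
               "fit in the frame")
})
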