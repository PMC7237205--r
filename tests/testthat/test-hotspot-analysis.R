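test_that("hybrid peak classes match an exhaustive overlap check", {
  f1 <- tibble::tibble(chrom = "chr1",
                       start = c(0, 100, 200, 300, 400, 500) * 10,
                       end = c(0, 100, 200, 300, 400, 500) * 10 + 50)
  b6 <- tibble::tibble(chrom = "chr1", start = c(0, 2000), end = c(60, 2040))
  cast <- tibble::tibble(chrom = "chr1", start = c(1000, 2000, 3000),
                         end = c(1050, 2050, 3010))
  out <- classify_hybrid_hotspots(f1, b6, cast)
  expect_equal(out$class, c("shared-B6", "shared-CAST", "shared-both",
                            "shared-CAST", "novel", "novel"))
  counts <- attr(out, "counts")
  expect_equal(sum(counts), nrow(f1))
  expect_equal(unname(counts["novel"]), 2L)
  expect_equal(sum(attr(out, "fractions")), 1)
})

test_that("dual-mark classes recover a planted composition exactly", {
  n <- 1000
  withr::with_seed(41, {
    start <- sort(sample(seq(0, 1e7, by = 3000), n))
  })
  peaks <- tibble::tibble(chrom = "chr1", start = start, end = start + 1000)
  cls <- rep(c("both", "K4-only", "K36-only", "neither"),
             times = c(850, 100, 30, 20))
  k4 <- peaks[cls %in% c("both", "K4-only"), ]
  k36 <- peaks[cls %in% c("both", "K36-only"), ]
  withr::with_seed(42, {
    peaks$strength <- rpois(n, ifelse(cls == "both", 150, 100))
  })
  out <- dual_mark_classes(peaks, k4, k36)
  expect_equal(unname(attr(out, "fractions")),
               c(0.85, 0.10, 0.03, 0.02))
  expect_equal(out$mark_class, cls)
  tests <- attr(out, "strength_tests")
  expect_true(all(tests$p < 0.01))
})

test_that("spike normalization is exactly scale-invariant and uses divisor 1/f", {
  hg <- toy_hotspot_genome(seed = 43, n = 10)
  lengths <- c(genome_lengths(hg$genome), chrSpike = 1e5)
  spk <- spike_spec("chrSpike", 5e4, fraction = 0.05)
  reads <- simulate_endseq(lengths, hg$truth, 5e4, spike = spk, seed = 44)
  centers <- tibble::tibble(chrom = hg$truth$chrom, pos = hg$truth$center)
  one <- spikein_normalize(reads, centers, spk, genome = lengths)
  expect_equal(one$divisor, 20)
  # duplicating every read leaves the normalized intensity unchanged
  dup <- spikein_normalize(dplyr::bind_rows(reads, reads), centers, spk,
                           genome = lengths)
  expect_equal(dup$normalized, one$normalized, tolerance = 1e-12)
  # zero spike signal is an error, not a silent zero
  no_spike <- dplyr::filter(reads, chrom != "chrSpike")
  expect_error(spikein_normalize(no_spike, centers, spk, genome = lengths),
               "spike")
})

test_that("doubled break rate with fixed spike doubles the normalized intensity", {
  hg <- toy_hotspot_genome(seed = 45, n = 20)
  lengths <- c(genome_lengths(hg$genome), chrSpike = 1e5)
  spk <- spike_spec("chrSpike", 5e4, fraction = 0.05)
  depth <- 2e5
  wt <- simulate_endseq(lengths, hg$truth, depth, spike = spk,
                        depth_ref = depth, seed = 46)
  dbl <- simulate_endseq(lengths, hg$truth, 2 * depth, spike = spk,
                         depth_ref = depth, seed = 47)
  centers <- tibble::tibble(chrom = hg$truth$chrom, pos = hg$truth$center)
  nw <- spikein_normalize(wt, centers, spk, genome = lengths)
  nd <- spikein_normalize(dbl, centers, spk, genome = lengths)
  expect_equal(nd$normalized / nw$normalized, 2, tolerance = 0.1)
})

test_that("central/flank decomposition separates a flank-only perturbation", {
  hg <- toy_hotspot_genome(seed = 48, n = 20)
  lengths <- c(genome_lengths(hg$genome), chrSpike = 1e5)
  spk <- spike_spec("chrSpike", 5e4, fraction = 0.05)
  centers <- tibble::tibble(chrom = hg$truth$chrom, pos = hg$truth$center)
  depth <- 2e5
  wt <- simulate_endseq(lengths, hg$truth, depth, genotype_flank_scale = 1,
                        spike = spk, depth_ref = depth, seed = 49)
  ko <- simulate_endseq(lengths, hg$truth, depth, genotype_flank_scale = 2,
                        spike = spk, depth_ref = depth, seed = 50)
  profs <- list(
    WT = anchor_profile(dplyr::select(wt, chrom, pos), centers, flank = 3000,
                        bin = 50, genome = lengths, row_order = "input"),
    KO = anchor_profile(dplyr::select(ko, chrom, pos), centers, flank = 3000,
                        bin = 50, genome = lengths, row_order = "input"))
  decomp <- central_flank_decomposition(profs)
  contrast <- genotype_contrast(decomp, "KO", "WT")
  expect_gt(contrast$flank_ratio, 1.5)
  expect_equal(contrast$central_ratio, 1, tolerance = 0.1)
  # identical samples give unit ratios exactly
  same <- central_flank_decomposition(list(A = profs$WT, B = profs$WT))
  expect_equal(genotype_contrast(same, "A", "B")$central_ratio, 1)
  expect_equal(genotype_contrast(same, "A", "B")$flank_ratio, 1)
})

test_that("strength correlation behaves at the rank-correlation extremes", {
  withr::with_seed(51, {
    tbl <- tibble::tibble(a = rnorm(50)) |>
      dplyr::mutate(b = -a, c = a)
  })
  self <- strength_correlation(tbl, "a", "c")
  expect_equal(self$rho, 1)
  neg <- strength_correlation(tbl, "a", "b")
  expect_equal(neg$rho, -1)
  expect_error(strength_correlation(tbl[1:5, ], "a", "b"), "at least")
  expect_error(
    strength_correlation(dplyr::mutate(tbl, d = 1), "a", "d"),
    "constant")
})
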