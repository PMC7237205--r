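test_that("length filter uses closed bounds", {
  fr <- tibble::tibble(chrom = "chr1", start = 1000,
                       end = 1000 + c(129, 130, 200, 201))
  kept <- filter_fragment_length(fr, 130, 200)
  expect_equal(kept$end - kept$start, c(130, 200))
  all_kept <- filter_fragment_length(fr, 0, Inf)
  expect_equal(nrow(all_kept), 4)
})

test_that("center-weighted coverage matches manual arithmetic at boundaries", {
  g <- c(chr1 = 10000)
  # [100,150): c = floor(249/2) = 124, bases 123-125 all in bin [100,150)
  t1 <- center_weighted_coverage(
    tibble::tibble(chrom = "chr1", start = 100, end = 150), g, bin = 50)
  expect_equal(t1$values$chr1[3], 3)
  expect_equal(sum(t1$values$chr1), 3)
  # [126,176): c = 150, bases {149,150,151} split 1 / 2 across bins 3 and 4
  t2 <- center_weighted_coverage(
    tibble::tibble(chrom = "chr1", start = 126, end = 176), g, bin = 50)
  expect_equal(t2$values$chr1[3:4], c(1, 2))
  # empty input
  t0 <- center_weighted_coverage(
    tibble::tibble(chrom = character(), start = numeric(), end = numeric()),
    g, bin = 50)
  expect_true(all(t0$values$chr1 == 0))
})

test_that("coverage equals a brute-force per-base accumulator and conserves mass", {
  chrom_len <- 10000
  withr::with_seed(11, {
    fr <- tibble::tibble(
      chrom = "chr1",
      start = sample(100:(chrom_len - 400), 1000, replace = TRUE)
    ) |> dplyr::mutate(end = start + sample(50:300, 1000, replace = TRUE))
  })
  track <- center_weighted_coverage(fr, c(chr1 = chrom_len), bin = 50)
  expect_identical(track$values$chr1,
                   oracle_center_coverage(fr, chrom_len, 50))
  expect_identical(sum(track$values$chr1), 3 * nrow(fr))
})

test_that("RPM and RPKM normalizations follow their formulas", {
  g <- c(chr1 = 10000)
  tr <- center_weighted_coverage(
    tibble::tibble(chrom = "chr1", start = 100, end = 150), g, 50)
  expect_equal(rpm_normalize(tr, 1e6)$values$chr1, tr$values$chr1)
  expect_equal(max(rpm_normalize(tr, 5e5)$values$chr1), 6)

  # 600 reads in a 6000 bp window with 1e6 total -> RPKM 100
  reads <- tibble::tibble(chrom = "chr1", pos = rep(3000, 600))
  win <- tibble::tibble(chrom = "chr1", start = 1000, end = 7000)
  expect_equal(window_rpkm(reads, win, total_reads = 1e6)$rpkm, 100)
  # empty window -> 0
  win0 <- tibble::tibble(chrom = "chr1", start = 8000, end = 9000)
  expect_equal(window_rpkm(reads, win0, total_reads = 1e6)$rpkm, 0)
  # whole-genome window: RPKM = 1e9 / genome_length regardless of depth
  winG <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  expect_equal(window_rpkm(reads, winG)$rpkm, 1e9 / 10000)
})

test_that("BEDPE fragments resolve to outer spans; discordant pairs skipped", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  withr::with_seed(3, {
    s1 <- sample(0:5000, 100)
  })
  df <- data.frame("chr1", s1, s1 + 50, "chr1", s1 + 120, s1 + 170,
                   paste0("frag", 1:100), 60, "+", "-")
  readr::write_tsv(df, path, col_names = FALSE)
  fr <- load_fragments(path, "bedpe")
  expect_equal(nrow(fr), 100)
  expect_equal(fr$length, rep(170, 100))

  # discordant record dropped with a warning
  df2 <- rbind(df, data.frame("chr1", 10, 60, "chr2", 100, 150,
                              "bad", 60, "+", "-") |>
                 stats::setNames(names(df)))
  readr::write_tsv(df2, path, col_names = FALSE)
  expect_warning(fr2 <- load_fragments(path, "bedpe"), "discordant")
  expect_equal(nrow(fr2), 100)

  empty <- withr::local_tempfile(fileext = ".bedpe")
  file.create(empty)
  expect_equal(nrow(load_fragments(empty, "bedpe")), 0)
})

test_that("SAM templates respect the strict MAPQ cutoff", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    # mapq 31 pair (kept), mapq 30 pair (dropped: cutoff is strict)
    "a\t99\tchr1\t101\t31\t50M\t=\t251\t200\t*\t*",
    "a\t147\tchr1\t251\t31\t50M\t=\t101\t-200\t*\t*",
    "b\t99\tchr1\t501\t30\t50M\t=\t651\t200\t*\t*",
    "b\t147\tchr1\t651\t30\t50M\t=\t501\t-200\t*\t*"
  )
  writeLines(lines, sam)
  fr <- load_fragments(sam, "sam", min_mapq = 30)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$start, 100)   # SAM 1-based -> BED 0-based
  expect_equal(fr$length, 200)
})

test_that("anchor profiles are symmetric for symmetric signal and flip minus strands", {
  hg <- toy_hotspot_genome(seed = 5, n = 15)
  fr <- simulate_cutrun(hg$genome, hg$truth, 2e5, signal_fraction = 1,
                        seed = 6)
  anchors <- tibble::tibble(chrom = hg$truth$chrom, pos = hg$truth$center)
  sm <- anchor_profile(fr, anchors, flank = 1000, bin = 50,
                       genome = genome_lengths(hg$genome))
  prof <- sm$mean_profile
  asym <- max(abs(prof - rev(prof))) / max(prof)
  expect_lt(asym, 0.05)

  # minus-strand anchor = reversed plus-strand profile
  one_plus <- anchors[1, ] |> dplyr::mutate(strand = "+")
  one_minus <- anchors[1, ] |> dplyr::mutate(strand = "-")
  sp <- anchor_profile(fr, one_plus, flank = 1000, bin = 50,
                       genome = genome_lengths(hg$genome))
  sn <- anchor_profile(fr, one_minus, flank = 1000, bin = 50,
                       genome = genome_lengths(hg$genome))
  expect_equal(sn$matrix[1, ], rev(sp$matrix[1, ]))
})

test_that("anchor profiles are translation-equivariant and flat on uniform input", {
  g <- c(chr1 = 1e6)
  withr::with_seed(12, {
    reads <- tibble::tibble(chrom = "chr1",
                            pos = sample(0:(1e6 - 1), 2e5, replace = TRUE))
    anchors <- tibble::tibble(chrom = "chr1",
                              pos = sample(5000:995000, 50))
  })
  sm <- anchor_profile(reads, anchors, flank = 1000, bin = 50, genome = g,
                       row_order = "input")
  cv <- stats::sd(sm$mean_profile) / mean(sm$mean_profile)
  expect_lt(cv, 0.10)

  delta <- 137
  sm2 <- anchor_profile(dplyr::mutate(reads, pos = pos + delta),
                        dplyr::mutate(anchors, pos = pos + delta),
                        flank = 1000, bin = 50, genome = g,
                        row_order = "input")
  expect_equal(sm2$matrix, sm$matrix)
})
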