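test_that("genome generation is deterministic by seed", {
  g1 <- generate_genome(1, c(chr1 = 1e5))
  g2 <- generate_genome(1, c(chr1 = 1e5))
  g3 <- generate_genome(2, c(chr1 = 1e5))
  expect_equal(nchar(g1$sequences$chr1), 1e5)
  expect_identical(g1$sequences, g2$sequences)
  expect_false(identical(g1$sequences$chr1, g3$sequences$chr1))
  expect_error(generate_genome(1, c(chr1 = 5000)), "10 kb")
})

test_that("hotspot planting writes motifs, spaces centers, and counts multis", {
  hg <- toy_hotspot_genome(seed = 81, n = 50, multi = 0.1,
                           lengths = c(chr1 = 1.2e6, chr2 = 6e5))
  truth <- hg$truth
  expect_equal(sum(truth$n_motifs == 2), 5)
  # spacing respected per chromosome
  by_chr <- split(truth$center, truth$chrom)
  for (p in by_chr) {
    if (length(p) > 1) expect_true(all(diff(sort(p)) >= 15000))
  }
  # planted motif present at each center on the declared strand
  for (i in seq_len(nrow(truth))) {
    m <- c(Dom2 = MOTIF_DOM2, Cast = MOTIF_CAST)[[truth$allele[i]]]
    if (truth$strand[i] == "-") {
      m <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    }
    s0 <- truth$center[i] - floor(nchar(m) / 2)
    seq <- hg$genome$sequences[[truth$chrom[i]]]
    expect_equal(substr(seq, s0 + 1, s0 + nchar(m)), m)
  }
  # allele mix near 50/50 (binomial 99% CI at n = 100)
  hg2 <- toy_hotspot_genome(seed = 82, n = 100,
                            lengths = c(chr1 = 1e6, chr2 = 6e5),
                            min_spacing = 12000)
  n_dom2 <- sum(hg2$truth$allele == "Dom2")
  expect_true(abs(n_dom2 - 50) < 2.58 * sqrt(100 * 0.25))
  # single hotspot perturbs only the motif window
  g0 <- generate_genome(83, c(chr1 = 5e4))
  one <- plant_hotspots(g0, 1, motifs = c(Dom2 = MOTIF_DOM2),
                        min_spacing = 1000, seed = 84)
  diffs <- which(strsplit(g0$sequences$chr1, "")[[1]] !=
                   strsplit(one$genome$sequences$chr1, "")[[1]])
  L <- nchar(MOTIF_DOM2)
  s0 <- one$truth$center - floor(L / 2)
  expect_true(all(diffs >= s0 + 1 & diffs <= s0 + L))
  # impossible packing errors out
  expect_error(plant_hotspots(g0, 100, motifs = c(Dom2 = MOTIF_DOM2),
                              min_spacing = 20000), "cannot place")
})

test_that("CUT&RUN simulation honours NDR exclusion and background uniformity", {
  hg <- toy_hotspot_genome(seed = 85, n = 10)
  # pure signal with NDR halfwidth 75: no midpoint within 75 bp of a center
  fr <- simulate_cutrun(hg$genome, hg$truth, 2e4, signal_fraction = 1,
                        ndr_halfwidth = 75, seed = 86)
  mids <- floor((fr$start + fr$end) / 2)
  dmin <- vapply(seq_len(nrow(fr)), function(i) {
    ctrs <- hg$truth$center[hg$truth$chrom == fr$chrom[i]]
    min(abs(ctrs - mids[i]))
  }, numeric(1))
  expect_true(all(dmin > 75))

  # pure background: midpoints indistinguishable from uniform (KS)
  fr0 <- simulate_cutrun(hg$genome, hg$truth, 5e3, signal_fraction = 0,
                         seed = 87)
  m1 <- fr0[fr0$chrom == "chr1", ]
  mid1 <- floor((m1$start + m1$end) / 2)
  ks <- suppressWarnings(
    stats::ks.test(mid1 / genome_lengths(hg$genome)[["chr1"]], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fragment-length truncation matches the analytic normal mass", {
  hg <- toy_hotspot_genome(seed = 88, n = 5)
  fr <- simulate_cutrun(hg$genome, hg$truth, 1e5, signal_fraction = 0.3,
                        seed = 89)
  kept <- filter_fragment_length(fr, 130, 200)
  expected <- (pnorm(200, 165, 15) - pnorm(130, 165, 15)) /
    (pnorm(250, 165, 15) - pnorm(100, 165, 15))
  expect_equal(attr(kept, "retained_fraction"), expected, tolerance = 0.02)
})

test_that("END-seq simulation respects central confinement and spike dosing", {
  hg <- toy_hotspot_genome(seed = 90, n = 10)
  lengths <- c(genome_lengths(hg$genome), chrSpike = 1e5)
  # central_fraction = 1: every bulk read within the central halfwidth
  reads <- simulate_endseq(lengths, hg$truth, 2e4, central_fraction = 1,
                           central_halfwidth = 250, seed = 91)
  d <- vapply(seq_len(nrow(reads)), function(i) {
    ctrs <- hg$truth$center[hg$truth$chrom == reads$chrom[i]]
    min(abs(ctrs - reads$pos[i]))
  }, numeric(1))
  expect_true(all(d <= 250))
  # no read beyond max_flank
  reads2 <- simulate_endseq(lengths, hg$truth, 2e4, central_fraction = 0.3,
                            max_flank = 3000, seed = 92)
  bulk <- reads2[reads2$origin != "spike", ]
  d2 <- vapply(seq_len(nrow(bulk)), function(i) {
    ctrs <- hg$truth$center[hg$truth$chrom == bulk$chrom[i]]
    min(abs(ctrs - bulk$pos[i]))
  }, numeric(1))
  expect_true(all(d2 <= 3000))

  # spike reads ~ Poisson(f * depth): within 3 sigma
  spk <- spike_spec("chrSpike", 5e4, 0.05)
  reads3 <- simulate_endseq(lengths, hg$truth, 1e5, spike = spk, seed = 93)
  n_spike <- sum(reads3$origin == "spike")
  expect_true(abs(n_spike - 5000) < 3 * sqrt(5000))

  # flank scaling doubles the flank/central ratio
  r_scale <- function(scale, seed) {
    r <- simulate_endseq(lengths, hg$truth, 1e5,
                         genotype_flank_scale = scale, seed = seed)
    sum(r$origin == "flank") / sum(r$origin == "central")
  }
  expect_equal(r_scale(2, 94) / r_scale(1, 95), 2, tolerance = 0.05)
})

test_that("copula UMI counts carry their planted correlations", {
  m <- simulate_sc_counts(200, 500, planted_rho = c(g_half = 0.5, g_null = 0),
                          seed = 96)
  norm <- normalize_counts(m)          # removes shared depth variation
  tgt <- norm["Prdm9", ]
  r_half <- cor(rank(norm["g_half", ]), rank(tgt))
  r_null <- cor(rank(norm["g_null", ]), rank(tgt))
  expect_equal(r_half, 0.5, tolerance = 0.1)
  expect_lt(abs(r_null), 0.1)
  # duplicated target correlates perfectly
  m2 <- rbind(m, clone = m["Prdm9", ])
  expect_equal(cor(rank(m2["clone", ]), rank(m2["Prdm9", ])), 1)
  # extreme rho rejected
  expect_error(simulate_sc_counts(10, 100, planted_rho = c(g = 0.99)),
               "0.95")
})

test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_sc_counts(20, 50, planted_rho = c(g = 0.4), seed = 97)
  b <- simulate_sc_counts(20, 50, planted_rho = c(g = 0.4), seed = 97)
  expect_identical(a, b)
  hg <- toy_hotspot_genome(seed = 98, n = 5)
  f1 <- simulate_cutrun(hg$genome, hg$truth, 1000, seed = 99)
  f2 <- simulate_cutrun(hg$genome, hg$truth, 1000, seed = 99)
  expect_identical(f1, f2)
  fam1 <- simulate_protein_families(n1 = 3, n2 = 3, seed = 100)
  fam2 <- simulate_protein_families(n1 = 3, n2 = 3, seed = 100)
  expect_identical(fam1, fam2)
  it1 <- simulate_itc(binding_params(2, -10), default_itc_schedule(),
                      noise_sd = 1, seed = 101)
  it2 <- simulate_itc(binding_params(2, -10), default_itc_schedule(),
                      noise_sd = 1, seed = 101)
  expect_identical(it1, it2)
})

test_that("protein families separate cleanly and flag the reference", {
  fam <- simulate_protein_families(n1 = 5, n2 = 5, seed = 102)
  mat <- meiohot:::msa_matrix(fam$msa)
  rownames(mat) <- names(fam$msa)
  pid <- function(a, b) mean(mat[a, ] == mat[b, ])
  f1 <- fam$truth$id[fam$truth$family == "family1"]
  f2 <- fam$truth$id[fam$truth$family == "family2"]
  within <- mean(c(pid(f1[1], f1[2]), pid(f2[1], f2[2])))
  between <- pid(f1[1], f2[1])
  expect_gt(within, between)
  expect_equal(fam$truth$id[fam$truth$is_reference], "F1_ref")
  # configurable inter-domain distances flow into the hit table
  d <- pair_domain_hits(fam$hits)
  expect_lt(nrow(d), nrow(fam$truth) + 1)   # the >50 kb loci drop out
})
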