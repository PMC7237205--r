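test_that("domain-hit pairing enforces the inclusive 50 kb rule", {
  mk_hits <- function(pw_start) tibble::tibble(
    species = "sp", subject = "acc",
    domain = c("zf-CW", "PWWP"),
    start = c(1000, pw_start), end = c(1165, pw_start + 200),
    score = c(50, 60))
  # gap between nearest ends: pw_start - 1165
  kept <- pair_domain_hits(mk_hits(1165 + 50000))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$distance, 50000)
  dropped <- pair_domain_hits(mk_hits(1165 + 50001))
  expect_equal(nrow(dropped), 0)
  # overlapping domains -> distance 0
  expect_equal(pair_domain_hits(mk_hits(1100))$distance, 0)
  # a subject with only one domain yields no candidate
  single <- mk_hits(2000)[2, ]
  expect_equal(nrow(pair_domain_hits(single)), 0)
})

test_that("domain-hit pairing is order-invariant and keeps the best pair", {
  hits <- tibble::tibble(
    species = "sp", subject = "acc",
    domain = c("zf-CW", "zf-CW", "PWWP"),
    start = c(1000, 3000, 4000), end = c(1200, 3200, 4200),
    score = c(10, 90, 50))
  a <- pair_domain_hits(hits)
  b <- pair_domain_hits(hits[c(3, 1, 2), ])
  expect_equal(a, b)
  expect_equal(a$zfcw_start, 3000)  # higher-scoring zf-CW hit wins
})

test_that("NJ reconstructs additive-distance topologies exactly", {
  # caterpillar tree on 8 leaves with known branch lengths
  tr <- ape::read.tree(text = paste0(
    "(((((((A:1,B:2):1,C:3):1,D:4):1,E:5):1,F:6):1,G:7):1,H:8):0;"))
  d <- ape::cophenetic.phylo(tr)
  nj <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
})

test_that("paralog assignment is perfect on clean two-clade families", {
  fam <- simulate_protein_families(n1 = 6, n2 = 6, seed = 71)
  f2_ref <- fam$truth$id[fam$truth$family == "family2"][1]
  out <- assign_paralog(fam$msa, family1_refs = "F1_ref",
                        family2_refs = f2_ref, outgroup = "outgroup",
                        n_bootstrap = 50, seed = 72)
  truth <- fam$truth$family[match(out$id, fam$truth$id)]
  expect_equal(out$family, truth)
  expect_true(all(out$support >= 0.95))
})

test_that("a candidate identical to a reference lands in its family with full support", {
  fam <- simulate_protein_families(n1 = 4, n2 = 4, seed = 73)
  msa <- fam$msa
  msa <- c(msa, candidate_clone = unname(msa[["F1_ref"]]))
  f2_ref <- fam$truth$id[fam$truth$family == "family2"][1]
  out <- assign_paralog(msa, "F1_ref", f2_ref, "outgroup",
                        n_bootstrap = 30, seed = 74)
  clone <- out[out$id == "candidate_clone", ]
  expect_equal(clone$family, "family1")
  expect_equal(clone$support, 1)
})

test_that("conservation profile drops reference gaps and matches analytic entropies", {
  msa <- c(ref = "AC-DF",
           s1  = "ACWDF",
           s2  = "ACWEF",
           s3  = "ACWE-")
  prof <- conservation_profile(msa, "ref")
  # reference has 4 ungapped residues; the gap column is dropped
  expect_equal(nrow(prof), 4)
  expect_equal(prof$ref_pos, 1:4)
  # invariant column: score 1, H = 0
  expect_equal(prof$score[1], 1)
  expect_equal(prof$entropy[1], 0)
  # column 4 (D,D,E,E): 50/50 -> H = 1 bit
  expect_equal(prof$entropy[3], 1)
  expect_equal(prof$score[3], 0.5)
  # column 5 has a gap in s3: frequencies renormalize over 3 residues
  expect_equal(prof$score[4], 1)

  # uniform 20-residue column -> H = log2(20)
  alpha <- c("A","C","D","E","F","G","H","I","K","L",
             "M","N","P","Q","R","S","T","V","W","Y")
  msa20 <- stats::setNames(alpha, paste0("s", 1:20))
  msa20[["s1"]] <- "A"; names(msa20)[1] <- "ref"
  prof20 <- conservation_profile(msa20, "ref")
  expect_equal(prof20$entropy, log2(20))
  # entropy bounds hold everywhere
  expect_true(all(prof$entropy >= 0 & prof$entropy <= log2(4)))
})

test_that("catalytic tallies map reference positions through gaps", {
  msa <- c(ref = "MAY-CYDYK",    # ungapped: MAYCYDYK, Y at 3, 5, 7
           s1  = "MAY-CYDYK",    # 3 conserved
           s2  = "MGY-CFDYK",    # Y, F, Y -> 2
           s3  = "MGF-CFDFK")    # 0
  tally <- catalytic_conservation(msa, "ref", positions = c(3, 5, 7),
                                  residue = "Y")
  expect_equal(tally$n_conserved[tally$id == "ref"], 3L)
  expect_equal(tally$n_conserved[tally$id == "s1"], 3L)
  expect_equal(tally$n_conserved[tally$id == "s2"], 2L)
  expect_equal(tally$n_conserved[tally$id == "s3"], 0L)
  # all-gap sequence at those columns counts zero
  msa[["s3"]] <- "MG--C-D-K"
  tally2 <- catalytic_conservation(msa, "ref", positions = c(3, 5, 7))
  expect_equal(tally2$n_conserved[tally2$id == "s3"], 0L)
  # reference residue mismatch is an error, not a guess
  expect_error(
    catalytic_conservation(msa, "ref", positions = c(1, 5, 7)),
    "isoform")
})

test_that("catalytic states requested from the generator appear in the alignment", {
  fam <- simulate_protein_families(
    n1 = 3, n2 = 3,
    catalytic_states = list(F2_sp01 = c(TRUE, TRUE, FALSE)),
    seed = 75)
  tally <- catalytic_conservation(fam$msa, "F1_ref")
  expect_equal(tally$n_conserved[tally$id == "F2_sp01"], 2L)
  expect_equal(tally$n_conserved[tally$id == "F1_ref"], 3L)
  expect_equal(fam$truth$n_catalytic[fam$truth$id == "F2_sp01"], 2L)
})

test_that("percent identity counts matches over shared non-gap columns", {
  msa <- c(a = "ACDEFGHIKL",
           b = "ACDWWWWWWW",
           c = "----------")
  expect_equal(percent_identity(msa, "a", "a"), 1)
  expect_equal(percent_identity(msa, "a", "b"), 0.3)
  expect_error(percent_identity(msa, "a", "c"), "non-gap")
})
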