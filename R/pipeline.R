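#' Default configuration for the end-to-end recipes
#'
#' Returns the full default parameter set used by [run_recipe()]; supply
#' a subset of the same structure to override fields.
#'
#' @return Nested list of per-stage parameters.
#' @export
default_config <- function() {
  list(
    genome = list(chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
                  spike_chrom_length = 1e5),
    hotspots = list(n = 60, min_spacing = 15000,
                    motifs = c(Dom2 = "CCTCCCTAGCCACG",
                               Cast = "AGGAATGCGTTGCA"),
                    allele_mix = c(Dom2 = 0.5, Cast = 0.5),
                    multi_motif_fraction = 0.1,
                    interval_halfwidth = 500),
    cutrun = list(n_fragments = 5e5, signal_fraction = 0.3,
                  frag_len = c(130, 200), bin = 50, flank = 1000),
    peaks = list(p_max = 0.001, merge_gap = 500, fold_min = 0),
    endseq = list(n_reads = 5e5, central_fraction = 0.5,
                  resection_mean = 1000, max_flank = 3000,
                  central_halfwidth = 250, spike_fraction = 0.05,
                  flank_scale_ko = 2),
    coexpr = list(n_genes = 200, n_cells = 1000, target = "Prdm9",
                  planted_rho = c(Zcwpw1 = 0.5, Sycp1 = 0.35,
                                  Hormad1 = 0.25),
                  top = 25),
    evo = list(n1 = 8, n2 = 8, n_bootstrap = 50),
    itc = list(K_D = 2, dH = -10, N = 1, V0 = 200, M0 = 25, X0 = 343,
               n_injections = 16, injection_volume = 2.5,
               noise_sd = 0)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run a simulate-then-analyse recipe end to end
#'
#' Six recipes tie the package's stages into the study's main analyses,
#' each on synthetic data with exported ground truth:
#' \describe{
#'   \item{cutrun-hotspots}{plant hotspots, simulate CUT&RUN, length-filter,
#'     center-weighted coverage, peak calling, motif-centered profile.}
#'   \item{endseq-contrast}{WT vs flank-scaled KO END-seq, spike-in
#'     normalization, central/flank decomposition and genotype contrast.}
#'   \item{hybrid-alleles}{F1 peak classification against parental maps and
#'     PWM-competitive allele assignment.}
#'   \item{coexpr-rank}{UMI simulation, normalization, Spearman ranking.}
#'   \item{evo-screen}{protein-family simulation, domain-hit pairing,
#'     paralog assignment, conservation profile, catalytic tally.}
#'   \item{itc-fit}{forward-model titration and one-set-of-sites fit.}
#' }
#' All randomness derives from `seed`; identical config + seed reproduce
#' identical results.
#'
#' @param name Recipe name.
#' @param config Optional nested list overriding [default_config()].
#' @param seed Integer seed (default 1).
#' @return Named list of result tables/objects, including a `summary`
#'   tibble and the `config` used.
#' @export
run_recipe <- function(name = c("cutrun-hotspots", "endseq-contrast",
                                "hybrid-alleles", "coexpr-rank",
                                "evo-screen", "itc-fit"),
                       config = list(), seed = 1) {
  name <- match.arg(name)
  cfg <- merge_config(default_config(), config)
  res <- switch(name,
    "cutrun-hotspots" = recipe_cutrun(cfg, seed),
    "endseq-contrast" = recipe_endseq(cfg, seed),
    "hybrid-alleles" = recipe_hybrid(cfg, seed),
    "coexpr-rank" = recipe_coexpr(cfg, seed),
    "evo-screen" = recipe_evo(cfg, seed),
    "itc-fit" = recipe_itc(cfg, seed))
  res$config <- cfg
  res
}

sim_hotspot_genome <- function(cfg, seed) {
  g <- generate_genome(seed, cfg$genome$chrom_lengths)
  plant_hotspots(g, n = cfg$hotspots$n, motifs = cfg$hotspots$motifs,
                 allele_mix = cfg$hotspots$allele_mix,
                 min_spacing = cfg$hotspots$min_spacing,
                 multi_motif_fraction = cfg$hotspots$multi_motif_fraction,
                 seed = seed + 1)
}

recipe_cutrun <- function(cfg, seed) {
  hg <- sim_hotspot_genome(cfg, seed)
  frags <- simulate_cutrun(hg$genome, hg$truth,
                           n_fragments = cfg$cutrun$n_fragments,
                           signal_fraction = cfg$cutrun$signal_fraction,
                           seed = seed + 2)
  kept <- filter_fragment_length(frags, cfg$cutrun$frag_len[1],
                                 cfg$cutrun$frag_len[2])
  track <- center_weighted_coverage(kept, genome_lengths(hg$genome),
                                    bin = cfg$cutrun$bin)
  peaks <- call_peaks(track, p_max = cfg$peaks$p_max,
                      merge_gap = cfg$peaks$merge_gap,
                      fold_min = cfg$peaks$fold_min)
  hits <- purrr::map(cfg$hotspots$motifs, function(m) {
    p <- pwm_from_consensus(m)
    scan_motif(hg$genome, p, threshold = 0.8 * max_score(p))
  }) |> purrr::list_rbind()
  anchors <- center_and_filter_hotspots(
    hotspot_intervals(hg$truth, cfg$hotspots$interval_halfwidth), hits)
  profile <- anchor_profile(kept, anchors, flank = cfg$cutrun$flank,
                            bin = cfg$cutrun$bin,
                            genome = genome_lengths(hg$genome))
  summary <- tibble(
    n_hotspots = nrow(hg$truth),
    n_fragments = nrow(frags),
    retained_fraction = attr(kept, "retained_fraction"),
    n_peaks = nrow(peaks),
    n_centered = attr(anchors, "exclusions")$n_centered,
    n_multi_excluded = attr(anchors, "exclusions")$n_multi
  )
  list(truth = hg$truth, fragments = kept, track = track, peaks = peaks,
       anchors = anchors, profile = profile, summary = summary)
}

recipe_endseq <- function(cfg, seed) {
  hg <- sim_hotspot_genome(cfg, seed)
  lengths <- c(genome_lengths(hg$genome),
               chrSpike = cfg$genome$spike_chrom_length)
  spk <- spike_spec("chrSpike", floor(cfg$genome$spike_chrom_length / 2),
                    cfg$endseq$spike_fraction)
  sim <- function(scale, s) {
    simulate_endseq(lengths, hg$truth, n_reads = cfg$endseq$n_reads,
                    central_fraction = cfg$endseq$central_fraction,
                    resection_mean = cfg$endseq$resection_mean,
                    max_flank = cfg$endseq$max_flank,
                    central_halfwidth = cfg$endseq$central_halfwidth,
                    genotype_flank_scale = scale, spike = spk,
                    depth_ref = cfg$endseq$n_reads, seed = s)
  }
  wt <- sim(1, seed + 2)
  ko <- sim(cfg$endseq$flank_scale_ko, seed + 3)
  centers <- tibble(chrom = hg$truth$chrom, pos = hg$truth$center)
  norm_wt <- spikein_normalize(wt, centers, spk, genome = lengths)
  norm_ko <- spikein_normalize(ko, centers, spk, genome = lengths)
  profs <- list(
    WT = anchor_profile(select(wt, "chrom", "pos"), centers,
                        flank = cfg$endseq$max_flank, bin = 50,
                        genome = lengths, row_order = "input"),
    KO = anchor_profile(select(ko, "chrom", "pos"), centers,
                        flank = cfg$endseq$max_flank, bin = 50,
                        genome = lengths, row_order = "input"))
  # per-sample spike divisor puts raw profiles on a per-break-rate scale
  spike_window <- tibble(chrom = spk$chrom,
                         start = max(0, spk$pos - 3000),
                         end = spk$pos + 3000)
  spike_cnt <- c(WT = window_rpkm(wt, spike_window)$count,
                 KO = window_rpkm(ko, spike_window)$count)
  scale_factors <- 1 / (spike_cnt / spk$fraction)
  decomp <- central_flank_decomposition(
    profs, scale_factors = scale_factors,
    central_halfwidth = cfg$endseq$central_halfwidth,
    flank_range = c(cfg$endseq$central_halfwidth, cfg$endseq$max_flank))
  contrast <- genotype_contrast(decomp, "KO", "WT")
  summary <- tibble(normalized_wt = norm_wt$normalized,
                    normalized_ko = norm_ko$normalized,
                    central_ratio = contrast$central_ratio,
                    flank_ratio = contrast$flank_ratio)
  list(truth = hg$truth, normalization = bind_rows(
         WT = norm_wt, KO = norm_ko, .id = "sample"),
       decomposition = decomp, contrast = contrast, summary = summary)
}

recipe_hybrid <- function(cfg, seed) {
  hg <- sim_hotspot_genome(cfg, seed)
  truth <- hg$truth
  iv <- hotspot_intervals(truth, cfg$hotspots$interval_halfwidth)
  iv$allele <- truth$allele
  # parental maps: B6 hotspots carry the Dom2 motif, CAST the Cast motif;
  # a random subset of each is "eroded" (absent from the parent), making
  # those F1 peaks novel
  withr::with_seed(seed + 5, {
    novel <- runif(nrow(iv)) < 0.2
  })
  b6 <- iv[iv$allele == "Dom2" & !novel, c("chrom", "start", "end")]
  cast <- iv[iv$allele == "Cast" & !novel, c("chrom", "start", "end")]
  classes <- classify_hybrid_hotspots(iv[, c("chrom", "start", "end")],
                                      b6, cast)
  pwm_d <- pwm_from_consensus(cfg$hotspots$motifs[["Dom2"]])
  pwm_c <- pwm_from_consensus(cfg$hotspots$motifs[["Cast"]])
  alleles <- assign_allele_by_motif(iv[, c("chrom", "start", "end")],
                                    hg$genome, pwm_d, pwm_c)
  acc <- mean(alleles$allele == truth$allele)
  summary <- tibble(n_peaks = nrow(iv),
                    n_novel = sum(classes$class == "novel"),
                    allele_accuracy = acc)
  list(truth = truth, classes = classes, alleles = alleles,
       summary = summary)
}

recipe_coexpr <- function(cfg, seed) {
  m <- simulate_sc_counts(cfg$coexpr$n_genes, cfg$coexpr$n_cells,
                          target_gene = cfg$coexpr$target,
                          planted_rho = cfg$coexpr$planted_rho,
                          seed = seed)
  norm <- normalize_counts(m)
  ranked <- spearman_coexpression(norm, cfg$coexpr$target)
  top_gene <- ranked$gene[ranked$gene != cfg$coexpr$target][1]
  summary <- tibble(top_gene = top_gene,
                    top_rho = ranked$rho[ranked$gene == top_gene])
  list(counts = m, coexpression = ranked, summary = summary)
}

recipe_evo <- function(cfg, seed) {
  fam <- simulate_protein_families(n1 = cfg$evo$n1, n2 = cfg$evo$n2,
                                   seed = seed)
  cand <- pair_domain_hits(fam$hits)
  assign <- assign_paralog(fam$msa,
                           family1_refs = "F1_ref",
                           family2_refs = fam$truth$id[
                             fam$truth$family == "family2"][1],
                           outgroup = "outgroup",
                           n_bootstrap = cfg$evo$n_bootstrap,
                           seed = seed + 1)
  prof <- conservation_profile(fam$msa, "F1_ref")
  tally <- catalytic_conservation(fam$msa, "F1_ref")
  correct <- mean(assign$family ==
                    fam$truth$family[match(assign$id, fam$truth$id)])
  summary <- tibble(n_candidate_loci = nrow(cand),
                    assignment_accuracy = correct,
                    mean_conservation = mean(prof$score, na.rm = TRUE))
  list(family = fam, candidates = cand, assignment = assign,
       conservation = prof, catalytic = tally, summary = summary)
}

recipe_itc <- function(cfg, seed) {
  sched <- itc_schedule(V0 = cfg$itc$V0, M0 = cfg$itc$M0, X0 = cfg$itc$X0,
                        injection_volumes = rep(cfg$itc$injection_volume,
                                                cfg$itc$n_injections))
  truth <- binding_params(cfg$itc$K_D, cfg$itc$dH, cfg$itc$N)
  heats <- simulate_itc(truth, sched, noise_sd = cfg$itc$noise_sd,
                        seed = seed)
  fit <- itc_fit(heats, sched)
  thermo <- derive_thermo(fit)
  summary <- glance.itc_fit(fit) |> bind_cols(thermo["dG"], thermo["dS"])
  list(heats = heats, fit = fit, thermo = thermo, summary = summary)
}

#' Maximum attainable log-odds score of a PWM
#' @param x A `pwm`.
#' @return Numeric scalar.
#' @export
max_score <- function(x) {
  sum(apply(x$log_odds, 1, max))
}
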