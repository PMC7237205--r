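# meiohot

Analysis toolkit for meiotic recombination hotspot mapping and
histone-methylation-reader binding, covering the computational stages used
to characterise a dual H3K4me3/H3K36me3 reader (such as ZCWPW1) acting
downstream of PRDM9:

* **CUT&RUN coverage** — fragment filtering (130–200 bp, MAPQ > 30),
  "trimmed-fragment" coverage where only the central three nucleotides of
  each fragment are counted into 50 bp bins, anchor-centered signal
  matrices for motif-centered heatmaps, and a documented Poisson window
  peak caller.
* **Hotspot logic** — PWM scanning of both strands with log-odds scores
  `sum(log2(p_base / bg_base))`, motif-centered hotspot filtering
  (hotspots with multiple motifs are excluded), F1-hybrid peak
  classification against parental maps (shared-B6 / shared-CAST /
  shared-both / novel), and competitive two-PWM allele assignment.
* **END-seq quantification** — spike-in normalization
  (`sum of hotspot-window RPKM / spike-window RPKM / (1/f)`, so a 5 %
  spike gives the divisor 20) and a central/flank decomposition that
  separates the break/invasion intermediate (±250 bp) from the resection
  flanks (250–3000 bp).
* **Single-cell co-expression** — median-ratio UMI normalization and
  Spearman ranking of all genes against a target gene (the screen that
  surfaces reader candidates co-expressed with *Prdm9*), with
  hierarchical cell ordering for heatmaps.
* **Ortholog evolution screen** — dual-domain (zf-CW + PWWP) hit pairing
  with an inclusive 50 kb inter-domain rule, neighbor-joining paralog
  assignment with column-bootstrap support, per-column conservation and
  Shannon entropy profiles along a reference, and catalytic-residue
  tallies (e.g. the PRDM9 SET-domain tyrosines Y276/Y341/Y357).
* **ITC binding** — the one-set-of-sites forward model
  (`theta^2 - theta(1 + X/(NM) + K_D/(NM)) + X/(NM) = 0`,
  `Q_i = N theta_i M_i dH V0`) with displaced-volume correction,
  Levenberg–Marquardt fitting of `(K_D, dH, N, baseline)`, and
  `dG = RT ln K_D`, `dS = (dH - dG)/T`.

A first-class synthetic-data module generates every input modality
(genomes with planted motif-anchored hotspots, CUT&RUN fragments with
phased-nucleosome structure around a nucleosome-depleted region, END-seq
reads with exponential resection flanks and a spike-in break locus,
copula-based UMI matrices with planted Spearman correlations, two-clade
protein families, ITC titrations) with exported ground truth, so the full
pipeline is testable without deposited sequencing data.

Everything is tidyverse-native: functions take tibbles (or simple named
vectors/matrices) and return tibbles, fitted objects have `tidy()` /
`glance()` / `autoplot()` methods, and results chain with the pipe.

## Worked example

```r
library(meiohot)

# CUT&RUN: simulate, filter, call peaks, center on motifs
r <- run_recipe("cutrun-hotspots", config = list(
  genome = list(chrom_lengths = c(chr1 = 1e6)),
  hotspots = list(n = 30), cutrun = list(n_fragments = 2e5)), seed = 42)
r$summary
#>   n_hotspots n_fragments retained_fraction n_peaks n_centered n_multi_excluded
#> 1         30      200000             0.983      51         27                3
```

30 hotspots were planted; after the 130–200 bp filter 98.3 % of fragments
remain (the truncated-normal length mass in that window), all 27
single-motif hotspots are motif-centered and the 3 multi-motif hotspots
are excluded, as the centering contract requires.

```r
# ITC: fit a noisy simulated titration (truth: K_D = 2 uM, dH = -10, N = 1)
sched <- itc_schedule(V0 = 200, M0 = 25, X0 = 343,
                      injection_volumes = rep(2.5, 16))
heats <- simulate_itc(binding_params(K_D = 2, dH = -10, N = 1), sched,
                      noise_sd = 0.5, seed = 42)
itc_fit(heats, sched)
#> <itc_fit> K_D = 1.263 uM, dH = -9.312 kcal/mol, N = 0.9843, baseline = 0.0621 ucal
#>   converged: TRUE, residual norm 1.85 ucal

# END-seq: knockout with doubled resection signal, unchanged break formation
run_recipe("endseq-contrast", seed = 42)$contrast
#>   central_ratio flank_ratio
#> 1          1.01        2.02
```

The decomposition reports the hallmark of a resection-extending genotype:
flanking signal doubles while the central (break-intermediate) signal is
unchanged.

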