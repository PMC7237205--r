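---
title: "Models and methods behind meiohot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiohot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiohot)
```

# Scope

`meiohot` implements the computational stages of a meiotic recombination
study centered on a dual histone-methylation reader: mapping where the
reader binds (CUT&RUN), quantifying double-strand-break formation and
resection (END-seq), resolving PRDM9-allele specificity in F1 hybrids,
ranking single-cell co-expression partners of *Prdm9*, screening genomes
for dual-domain orthologs, and fitting peptide-binding isotherms. Because
the original deposited sequencing data are not required, a seeded
synthetic-data module generates each input modality together with its
ground truth; every downstream claim in the test suite is checked against
that truth, not against copied constants.

# Coverage model

**Fragments.** A fragment is the outer span of a properly paired read
pair in 0-based half-open coordinates. Templates are retained only when
mapping quality is *strictly* greater than 30 — we read the stated
quality cutoff as MAPQ, the only per-template quality available at this
stage, and treat the bound as exclusive, so MAPQ 30 is dropped and 31
kept. Length selection keeps the closed range 130–200 bp, the
mono-nucleosome-protected population.

**Center-weighted coverage.** Only the central three nucleotides of each
fragment are counted: for `[start, end)` the center base is
`c = floor((start + end - 1)/2)` and bases `c-1, c, c+1` each contribute
one unit to genome-anchored 50 bp bins (bin *k* covers
`[50k, 50(k+1))`). The floor-based center is our choice for even-length
fragments, where no unique central base exists. Mass is split across
bins when the three bases straddle a boundary — counting each nucleotide
where it lies, rather than assigning all three to the center's bin —
so total track mass is exactly `3 × fragment count` away from chromosome
edges, an invariant tested exactly against a per-base brute-force
accumulator.

**Anchor profiles.** Signal matrices around anchors (motif centers,
merged TSS) use anchor-aligned offset bins over `[-flank, +flank)`;
minus-strand anchors are column-reversed; anchors within `flank` of a
chromosome edge are dropped with a warning. Row order defaults to
descending row sum, the common display convention for such heatmaps.

**Anchor merging.** TSS/TES-style anchors are merged by single-linkage
chaining at radius 500 bp and recentered at the floored midpoint of each
cluster's extremes. Chaining was chosen because it matches common merge
tools and makes the operation idempotent (verified by property test);
midpoint recentering is our choice where the procedure is otherwise
underdetermined. Merging is strand-blind.

# Peak calling

The caller is an intentionally simple, fully documented Poisson window
test, not a reimplementation of MACS: per-bin background
`lambda = max(global mean, depth-scaled control mean)`, where the control
mean is the larger of the control bin itself and a running mean over a
1 kb window around it. The per-bin component suppresses sharp artefacts
shared with the control; the running mean prevents a single
downward-fluctuating control bin from licensing a false peak. A bin with
count `x` is significant iff `P(X >= x | lambda) <= p_max` (default
0.001); significant bins within `merge_gap` merge into one peak
(500 bp default for broad CUT&RUN signal, ~1 kb recommended for END-seq
scale); fold enrichment is the maximum bin count over its `lambda`, and
the END-seq retention rule keeps peaks with fold > 2.5. Because the fold
definition is ours, absolute peak counts are not comparable with numbers
produced by other callers, and externally called peak BED files can be
substituted anywhere downstream. There is no deduplication in this
module, matching keep-all-duplicates END-seq practice, and no q-value
machinery. Type-I control, planted-site recall and threshold
monotonicity are property-tested.

# Motif and allele logic

PWMs carry probabilities with a 0.01 per-base pseudocount; scores are
`sum(log2(p/background))`. Both strands are scanned (the reverse strand
via the reverse-complemented matrix), and overlapping hits are resolved
greedily best-score-first with leftmost-then-plus tie-breaks; the scanner
is tested for exact equality against brute-force enumeration. Hotspots
are motif-centered only when they contain exactly one hit: multi-motif
hotspots are excluded, and zero-hit hotspots necessarily drop out as
well since there is nothing to center on — both counts are reported.
Allele assignment is competitive: the best in-hotspot score of each
allele's PWM, with a 1-bit default margin below which the call is
ambiguous. F1 peaks are classed against parental maps by any-overlap
(≥ 1 bp); peaks overlapping neither parental map are "novel", the
hybrid-specific category.

# END-seq normalization and decomposition

Spike-in normalization follows the stated order of operations literally:
total intensity is the sum of RPKM over ±3 kb windows around hotspot
centers, divided by the RPKM around the spike-in break locus, then
divided by `1/f` (20 at the 5 % mixing fraction). RPKM assigns a read to
a window iff its 5′ end falls inside, since END-seq read 5′ ends mark
break-proximal positions. The quantity is exactly invariant to global
depth rescaling — duplicating every read changes nothing — which is what
makes cross-genotype comparisons meaningful. The spike window half-width
(±3 kb, matching the hotspot windows) is configurable since the original
description leaves it open.

The central/flank decomposition summarises each sample's mean hotspot
profile as a central component (±250 bp, tracking the unresected
break/invasion intermediate) and a flanking component (250–3000 bp both
sides, tracking resection endpoints). These window sizes are package
defaults, not published values — the underlying contrast was qualitative
— so they are parameters with their choice recorded in output. The
synthetic END-seq generator places flank reads at
`center ± (central_halfwidth + d)` with `d ~ Exponential(resection_mean)`
truncated so no read exceeds `max_flank`: measuring the exponential
offset from the edge of the central zone keeps the two windows
identifiable (resection tracts extend beyond the break-proximal region)
and makes the planted flank-only perturbation recoverable as a flank
ratio of 2 with a central ratio of 1.

# Single-cell co-expression

UMI counts are normalized with median-ratio size factors
(`cell total / median of totals`) followed by `log2(x + 1)`. This is a
deliberately simple, documented scheme rather than a pooled
normalization: the downstream statistic is rank-based, so sensitivity to
the normalization flavour is low, and the property suite verifies that
normalization removes depth-driven rank correlation between independent
genes. Spearman's rho uses average ranks; p-values use the t
approximation `t = rho sqrt((n-2)/(1-rho^2))` for large n and exact
permutation enumeration for n ≤ 10. Genes expressed in fewer than 5 % of
cells are excluded by default to avoid degenerate ranks. We default to
correlating *normalized* counts (raw counts are also accepted): with
variable per-cell depth, raw-count correlations are inflated by the
shared depth factor, which the tests demonstrate directly. Cell ordering
for heatmaps uses euclidean distance with complete linkage, ties broken
deterministically by column index.

The synthetic UMI generator is a Gaussian copula: one latent normal per
cell drives the target gene, each planted gene's latent correlates with
it at the Pearson level `2 sin(pi rho / 6)` so the *latent* Spearman
correlation equals the planted value, and latents map to counts through
the Poisson quantile function with per-gene means and per-cell depth
factors. Discretization ties and size-factor estimation noise attenuate
the recovered rho slightly; with a realistic number of genes (≥ 100,
so size factors are stable) recovery at 500–1000 cells sits within ±0.1
of the planted value, which is the generator's tested contract.
Requested |rho| > 0.95 is rejected because copula discretization distorts
extreme correlations.

# Ortholog screen and conservation

Candidate loci require one hit for each of the two domains (zf-CW and
PWWP) on the same subject, with the gap between the nearest ends of the
two aligned regions at most 50 kb — the bound is inclusive, reading
"does not exceed" literally, and the boundary is tested at
50,000/50,001. Paralog assignment replaces maximum-likelihood tree
search with neighbor joining on p-distances (pairwise gap deletion) plus
column bootstrap: the decision needed is only which side of the
family-1/family-2 bipartition a candidate falls on, which NJ recovers
exactly on clean data (verified against additive-distance toys and
planted two-clade families), and the substitution is recorded in output
metadata. Assignment walks from the candidate tip rootward; the first
ancestral clade containing any reference decides the family, and a clade
containing both families' references yields "unresolved".

Conservation profiles drop columns where the reference is gapped, so the
profile length equals the reference's ungapped length; within a column,
gaps are excluded and frequencies renormalized, the score is the maximum
residue frequency (a documented stand-in for proprietary alignment-viewer
scores) and entropy is Shannon's `−sum(p log2 p)` in bits, checked
against the analytic values 0, 1, and log2 20. Catalytic-residue
tallies map 1-based ungapped reference positions (default the three
SET-domain tyrosines 276/341/357) to alignment columns by cumulative
non-gap count; if the reference itself lacks the queried residue at a
position the function raises an error rather than guessing, because that
indicates isoform-numbering mismatch.

# ITC model

The one-set-of-sites forward model solves, per injection, the quadratic
for the bound fraction `theta` in `[0,1]`, with cumulative heat
`Q_i = N theta_i M_i dH V0` and observed heat
`dQ_i = Q_i − Q_{i−1} + (v_i/V0)(Q_i + Q_{i−1})/2 + baseline`. Dilution
uses the continuous-displacement convention
(`M_i = M0 exp(−V_i/V0)`, `X_i = X0 (1 − exp(−V_i/V0))`); instrument
vendors differ here, the convention is documented, and the fit inverts
the same forward model so parameter recovery is convention-consistent.
Units are fixed (µM, µL, kcal/mol, µcal). Fitting is Levenberg–Marquardt
over `(log K_D, dH, N, baseline)` — K_D on the log scale for
stability — initialized with `N = 1`, `dH` from the mean of the first
three heats assuming complete early binding, and `K_D` from a
steepest-slope heuristic on the normalized isotherm. Noiseless
self-consistency holds to better than 1e-4 relative across Wiseman
c-values 1–1000, and non-convergence is flagged, never silently
returned. `dG = RT ln K_D` (K_D in molar) and `dS = (dH − dG)/T` close
the thermodynamic identity to machine precision. The default schedule
mirrors the dual-mark peptide experiment: 25 µM protein in the cell,
343 µM peptide in the syringe, 16 × 2.5 µL injections, with a 200 µL
cell (a typical automated-ITC cell volume; the cell volume is not stated
in the experimental description).

# What the generators do and do not emulate

The synthetic module reproduces the *structural* features the analyses
depend on: phased nucleosomal signal symmetric around a depleted center
(signal fragment midpoints at ±1/±2 nucleosome spacings, never within
the NDR half-width), truncated-normal fragment lengths (165 ± 15 bp,
clipped to 100–250 bp, chosen so the 130–200 bp filter removes an
analytically known mass), exponential resection flanks, a spike-in break
locus dosed at `f ×` reference depth, lognormal hotspot strengths, and
two-clade protein families with conserved domain blocks. It does not
emulate sequence composition bias, mappability, PCR duplication,
sequencing error, chromatin background structure, or real hotspot
spacing distributions; passing tests therefore demonstrate correctness
of the computations under clean planted truth, not robustness to every
artefact of real libraries. Hotspot centers are placed by sorted-uniform
sampling stretched by the minimum spacing, which respects the spacing
constraint exactly without rejection-sampling failures near capacity.

# Problem sizes and determinism

The test suite runs the statistical checks at the scale their tolerances
assume — about 10^6 reads/fragments for the spike-in ratio and
decomposition checks, a 10 Mb track with 50 planted sites for
peak-caller recall, 1000 cells for co-expression recovery — which keeps
the full suite under a minute of simulation-heavy work. Every generator
threads a single integer seed through `withr::local_seed`, so identical
calls are byte-identical and the caller's RNG state is never disturbed;
recipe outputs embed the full configuration used.

# Known limitations

* The peak caller's fold-enrichment definition (max bin over lambda) is
  not comparable to other callers' absolute peak counts.
* Allele classification operates on a single reference genome with
  planted motif variants; allele-aware alignment of hybrid reads is out
  of scope.
* NJ paralog assignment is a bipartition decision, not a full phylogeny;
  deep or rate-heterogeneous families should be assigned with an
  external ML tree, which can be supplied since alignments are inputs.
* The exact-permutation Spearman p is limited to n ≤ 10 (10! orderings);
  beyond that the t approximation is used.
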