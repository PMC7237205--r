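# truncated-normal sampler via inverse CDF (closed interval [lo, hi])
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# exponential truncated at tmax, via inverse CDF
rtruncexp <- function(n, mean, tmax) {
  u <- runif(n, 0, 1 - exp(-tmax / mean))
  -mean * log(1 - u)
}

#' Simulate CUT&RUN fragments around planted hotspots
#'
#' Emulates the structure of nucleosome-footprint CUT&RUN data at
#' PRDM9-bound hotspots: a central nucleosome-depleted region (NDR) with
#' symmetrically phased signal at the +/-1 and +/-2 nucleosome positions.
#' Signal fragment midpoints sit at `center +/- k * nucleosome_spacing`
#' (k = 1 with probability 0.6, else 2) plus Gaussian jitter, resampled so
#' no signal midpoint falls within `ndr_halfwidth` of the center.
#' Background fragment midpoints are uniform over the genome. Fragment
#' lengths are truncated-normal, so a downstream 130-200 bp length filter
#' removes an analytically known fraction.
#'
#' @param genome A `synthetic_genome` (typically from [plant_hotspots()]).
#' @param truth Hotspot truth tibble; signal is allocated across hotspots
#'   proportionally to `strength`.
#' @param n_fragments Total number of fragments.
#' @param signal_fraction Fraction of fragments that are hotspot signal
#'   (in \[0, 1\]).
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp),
#'   default 165 +/- 15.
#' @param len_clip Closed truncation interval for lengths (default
#'   `c(100, 250)`).
#' @param ndr_halfwidth NDR half-width (bp, default 75): no signal
#'   midpoint within this distance of a center.
#' @param nucleosome_spacing Nucleosome phasing distance (bp, default 180).
#' @param jitter_sd Gaussian jitter of nucleosome positions (bp, default
#'   20).
#' @param seed Optional seed.
#' @return Fragment tibble (`chrom`, `start`, `end`, `length`) with
#'   attribute `truth_origin` (`"signal"`/`"background"` per fragment).
#' @export
simulate_cutrun <- function(genome, truth, n_fragments,
                            signal_fraction = 0.5,
                            frag_len_mean = 165, frag_len_sd = 15,
                            len_clip = c(100, 250),
                            ndr_halfwidth = 75, nucleosome_spacing = 180,
                            jitter_sd = 20, seed = NULL) {
  stopifnot(signal_fraction >= 0, signal_fraction <= 1)
  lengths <- genome_lengths(genome)
  local_seed_if(seed)
  margin <- 2 * nucleosome_spacing + 6 * jitter_sd + ceiling(len_clip[2] / 2)
  if (signal_fraction > 0 && nrow(truth) > 0) {
    bad <- truth$center < margin | truth$center > lengths[truth$chrom] - margin
    if (any(bad)) abort("hotspot too close to a chromosome edge for flanks")
  }
  n_signal <- round(n_fragments * signal_fraction)
  n_bg <- n_fragments - n_signal

  sig <- NULL
  if (n_signal > 0) {
    hs <- sample.int(nrow(truth), n_signal, replace = TRUE,
                     prob = truth$strength)
    k <- sample(c(1, 2), n_signal, replace = TRUE, prob = c(0.6, 0.4))
    side <- sample(c(-1, 1), n_signal, replace = TRUE)
    offset <- k * nucleosome_spacing + rnorm(n_signal, 0, jitter_sd)
    redo <- which(offset <= ndr_halfwidth)
    while (length(redo)) {
      offset[redo] <- k[redo] * nucleosome_spacing +
        rnorm(length(redo), 0, jitter_sd)
      redo <- redo[offset[redo] <= ndr_halfwidth]
    }
    sig <- tibble(chrom = truth$chrom[hs],
                  mid = truth$center[hs] + side * round(offset),
                  origin = "signal")
  }
  bg <- NULL
  if (n_bg > 0) {
    chrom <- sample(names(lengths), n_bg, replace = TRUE,
                    prob = lengths / sum(lengths))
    bg <- tibble(chrom = chrom,
                 mid = floor(runif(n_bg, ceiling(len_clip[2] / 2),
                                   lengths[chrom] - ceiling(len_clip[2] / 2))),
                 origin = "background")
  }
  frags <- bind_rows(sig, bg)
  len <- round(rtruncnorm_inv(nrow(frags), frag_len_mean, frag_len_sd,
                              len_clip[1], len_clip[2]))
  out <- tibble(chrom = frags$chrom,
                start = frags$mid - floor(len / 2),
                end = frags$mid - floor(len / 2) + len,
                length = len)
  keep <- out$start >= 0 & out$end <= lengths[out$chrom]
  out <- out[keep, ]
  attr(out, "truth_origin") <- frags$origin[keep]
  out
}

#' Specify an END-seq spike-in
#'
#' Describes the exogenous control cells carrying a single engineered
#' double-strand break, mixed into the bulk sample at fraction `f`.
#'
#' @param chrom Spike chromosome name (must be distinct from bulk
#'   chromosomes).
#' @param pos Break position (bp, 0-based).
#' @param fraction Mixing fraction f in (0, 1); default 0.05 (a 1:20
#'   ratio).
#' @return List with class `spike_spec`.
#' @export
spike_spec <- function(chrom, pos, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) abort("spike fraction must be in (0, 1)")
  if (pos < 0) abort("spike position must be non-negative")
  structure(list(chrom = chrom, pos = pos, fraction = fraction),
            class = "spike_spec")
}

#' Simulate END-seq 5'-end reads at hotspots with resection flanks
#'
#' Per hotspot, a `central_fraction` of bulk reads falls uniformly within
#' `+/- central_halfwidth` of the center (the unresected break/invasion
#' intermediate); the remainder are resection-endpoint reads placed at
#' `center +/- (central_halfwidth + d)` with `d ~ Exponential(
#' resection_mean)` truncated so no read lies beyond `max_flank`.
#' `genotype_flank_scale` multiplies the number of flanking reads only,
#' modelling a genotype with unchanged break formation but increased
#' resection signal. Spike-in reads are added at the spike break locus
#' with expected count `fraction * depth_ref`.
#'
#' @param genome A `synthetic_genome` or genome declaration; must include
#'   the spike chromosome when a spike is given.
#' @param truth Hotspot truth tibble; reads allocated proportionally to
#'   `strength`.
#' @param n_reads Bulk read count before flank scaling.
#' @param central_fraction Fraction of bulk reads in the central window.
#' @param resection_mean Mean resection tract length (bp, default 1000).
#' @param max_flank Maximum distance of any read from its center (bp,
#'   default 3000).
#' @param central_halfwidth Central window half-width (bp, default 250).
#' @param genotype_flank_scale Multiplier on flanking read counts
#'   (default 1).
#' @param spike A [spike_spec()], or NULL for no spike-in.
#' @param depth_ref Reference depth for the spike expectation; defaults to
#'   `n_reads` (hold it fixed when comparing genotypes of different
#'   depth).
#' @param seed Optional seed.
#' @return Read tibble (`chrom`, `pos`, `origin` in
#'   central/flank/spike).
#' @export
simulate_endseq <- function(genome, truth, n_reads, central_fraction = 0.5,
                            resection_mean = 1000, max_flank = 3000,
                            central_halfwidth = 250,
                            genotype_flank_scale = 1, spike = NULL,
                            depth_ref = n_reads, seed = NULL) {
  if (resection_mean > max_flank) abort("resection_mean must be <= max_flank")
  if (central_fraction < 0 || central_fraction > 1) {
    abort("central_fraction must be in [0, 1]")
  }
  lengths <- genome_lengths(genome)
  if (!is.null(spike)) {
    stopifnot(inherits(spike, "spike_spec"))
    if (!spike$chrom %in% names(lengths)) {
      abort("spike chromosome missing from genome declaration")
    }
    if (spike$chrom %in% truth$chrom) {
      abort("spike chromosome must be distinct from bulk chromosomes")
    }
  }
  local_seed_if(seed)
  n_central <- round(n_reads * central_fraction)
  n_flank <- round(n_reads * (1 - central_fraction) * genotype_flank_scale)

  mk <- function(n, flank) {
    if (n == 0) return(NULL)
    hs <- sample.int(nrow(truth), n, replace = TRUE, prob = truth$strength)
    if (!flank) {
      off <- sample(seq(-central_halfwidth, central_halfwidth), n,
                    replace = TRUE)
    } else {
      d <- rtruncexp(n, resection_mean, max_flank - central_halfwidth)
      off <- sample(c(-1, 1), n, replace = TRUE) *
        round(central_halfwidth + d)
    }
    tibble(chrom = truth$chrom[hs], pos = truth$center[hs] + off,
           origin = if (flank) "flank" else "central")
  }
  reads <- bind_rows(mk(n_central, FALSE), mk(n_flank, TRUE))
  if (!is.null(spike)) {
    n_spike <- rpois(1, spike$fraction * depth_ref)
    if (n_spike > 0) {
      reads <- bind_rows(reads, tibble(
        chrom = spike$chrom,
        pos = spike$pos + sample(seq(-central_halfwidth, central_halfwidth),
                                 n_spike, replace = TRUE),
        origin = "spike"))
    }
  }
  reads <- reads[reads$pos >= 0 & reads$pos < lengths[reads$chrom], ]
  reads
}
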