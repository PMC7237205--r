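#' Classify F1-hybrid peaks against parental hotspot maps
#'
#' Every F1 peak is labeled by 1-bp overlap with the two parental hotspot
#' sets: `shared-B6`, `shared-CAST`, `shared-both`, or `novel` (overlapping
#' neither map — the hybrid-specific hotspots created when each PRDM9
#' allele binds the other subspecies' genome).
#'
#' @param f1_peaks Interval tibble of F1-hybrid peaks.
#' @param parental_b6,parental_cast Interval tibbles of parental hotspots.
#' @return `f1_peaks` with a `class` column; attributes `counts` and
#'   `fractions` summarise the four classes.
#' @export
classify_hybrid_hotspots <- function(f1_peaks, parental_b6, parental_cast) {
  check_intervals(f1_peaks, what = "f1_peaks")
  g <- as_granges0(f1_peaks)
  in_b6 <- if (nrow(parental_b6)) {
    GenomicRanges::countOverlaps(g, as_granges0(parental_b6)) > 0
  } else rep(FALSE, nrow(f1_peaks))
  in_cast <- if (nrow(parental_cast)) {
    GenomicRanges::countOverlaps(g, as_granges0(parental_cast)) > 0
  } else rep(FALSE, nrow(f1_peaks))
  out <- f1_peaks |>
    mutate(class = case_when(
      in_b6 & in_cast ~ "shared-both",
      in_b6 ~ "shared-B6",
      in_cast ~ "shared-CAST",
      TRUE ~ "novel"
    ))
  lv <- c("shared-B6", "shared-CAST", "shared-both", "novel")
  counts <- table(factor(out$class, levels = lv))
  attr(out, "counts") <- setNames(as.integer(counts), lv)
  attr(out, "fractions") <- setNames(as.numeric(counts) / nrow(out), lv)
  out
}

#' Dual histone-mark classes at peaks
#'
#' Classifies each peak by 1-bp overlap with H3K4me3 and H3K36me3 peak
#' sets into `both`, `K4-only`, `K36-only`, `neither`, and compares peak
#' strengths between the dual-marked class and each single-marked class
#' with one-sided Wilcoxon rank-sum tests (alternative: dual > single).
#'
#' @param peaks Interval tibble with a `strength` column (see
#'   [peak_strength()]).
#' @param k4_peaks,k36_peaks Interval tibbles of the two histone-mark peak
#'   sets.
#' @return `peaks` with a `mark_class` column; attributes `fractions`
#'   (sums to 1) and `strength_tests` (tibble of rank-sum comparisons).
#' @export
dual_mark_classes <- function(peaks, k4_peaks, k36_peaks) {
  check_intervals(peaks, what = "peaks")
  g <- as_granges0(peaks)
  k4 <- if (nrow(k4_peaks)) {
    GenomicRanges::countOverlaps(g, as_granges0(k4_peaks)) > 0
  } else rep(FALSE, nrow(peaks))
  k36 <- if (nrow(k36_peaks)) {
    GenomicRanges::countOverlaps(g, as_granges0(k36_peaks)) > 0
  } else rep(FALSE, nrow(peaks))
  out <- peaks |>
    mutate(mark_class = case_when(
      k4 & k36 ~ "both",
      k4 ~ "K4-only",
      k36 ~ "K36-only",
      TRUE ~ "neither"
    ))
  lv <- c("both", "K4-only", "K36-only", "neither")
  fr <- table(factor(out$mark_class, levels = lv)) / nrow(out)
  attr(out, "fractions") <- setNames(as.numeric(fr), lv)
  if ("strength" %in% names(out)) {
    tests <- map(c("K4-only", "K36-only"), function(single) {
      a <- out$strength[out$mark_class == "both"]
      b <- out$strength[out$mark_class == single]
      if (length(a) < 2L || length(b) < 2L) {
        return(tibble(comparison = paste0("both vs ", single),
                      p = NA_real_, n_both = length(a), n_single = length(b)))
      }
      w <- wilcox.test(a, b, alternative = "greater", exact = FALSE)
      tibble(comparison = paste0("both vs ", single), p = w$p.value,
             n_both = length(a), n_single = length(b))
    }) |> list_rbind()
    attr(out, "strength_tests") <- tests
  }
  out
}

#' Spike-in normalized END-seq intensity
#'
#' Total END-seq intensity (sum of RPKM over hotspot windows, by default
#' +/- 3 kb around each hotspot center) is divided by the RPKM around the
#' spike-in break locus and then by `1/f`; with the spike mixed at
#' `f = 0.05` (a 1:20 ratio) the final divisor is 20. The result is
#' invariant to global sequencing-depth rescaling, so genotypes can be
#' compared on a per-break-rate scale.
#'
#' @param reads Tibble of 5'-end positions (`chrom`, `pos`).
#' @param hotspot_centers Tibble with `chrom`, `pos` of hotspot centers, or
#'   an interval tibble of ready-made windows.
#' @param spike List with `chrom`, `pos` (break position) and `fraction`
#'   (mixing fraction f in (0,1)), as produced by [spike_spec()].
#' @param window_halfwidth Hotspot window half-width in bp (default 3000).
#' @param spike_halfwidth Spike window half-width in bp (default 3000).
#' @param genome Genome declaration, used to clip windows.
#' @return One-row tibble: `hotspot_rpkm`, `spike_rpkm`, `divisor`,
#'   `normalized`.
#' @export
spikein_normalize <- function(reads, hotspot_centers, spike,
                              window_halfwidth = 3000,
                              spike_halfwidth = 3000, genome = NULL) {
  if (spike$fraction <= 0 || spike$fraction >= 1) {
    abort("spike fraction must be in (0, 1)")
  }
  windows <- if (all(c("start", "end") %in% names(hotspot_centers))) {
    hotspot_centers
  } else {
    tibble(chrom = hotspot_centers$chrom,
           start = pmax(0, hotspot_centers$pos - window_halfwidth),
           end = hotspot_centers$pos + window_halfwidth)
  }
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    windows$end <- pmin(windows$end, genome[windows$chrom])
  }
  total <- nrow(reads)
  hs <- window_rpkm(reads, windows, total_reads = total)
  spike_window <- tibble(chrom = spike$chrom,
                         start = max(0, spike$pos - spike_halfwidth),
                         end = spike$pos + spike_halfwidth)
  sp <- window_rpkm(reads, spike_window, total_reads = total)
  if (sp$count == 0) abort("zero reads in spike window; cannot normalize")
  divisor <- 1 / spike$fraction
  tibble(hotspot_rpkm = sum(hs$rpkm),
         spike_rpkm = sp$rpkm,
         divisor = divisor,
         normalized = sum(hs$rpkm) / sp$rpkm / divisor)
}

#' Central / flanking decomposition of hotspot profiles
#'
#' Splits each sample's mean hotspot profile into a central component
#' (mean signal within `+/- central_halfwidth` of the hotspot center,
#' tracking the unresected break/invasion intermediate) and a flanking
#' component (mean signal over `flank_range` bp on both sides, tracking
#' the extent of end resection). Profiles can optionally be rescaled by
#' per-sample spike-normalization factors before decomposition.
#'
#' @param profiles Named list of `signal_matrix` objects (one per sample),
#'   all with flank at least `max(flank_range)`.
#' @param scale_factors Optional named numeric vector of per-sample scale
#'   factors (e.g. spike-normalized intensities per raw read).
#' @param central_halfwidth Central window half-width in bp (default 250).
#' @param flank_range Length-2 numeric, flanking window as distance from
#'   center in bp (default `c(250, 3000)`).
#' @return Tibble with one row per sample: `sample`, `central`, `flank`.
#' @export
central_flank_decomposition <- function(profiles, scale_factors = NULL,
                                        central_halfwidth = 250,
                                        flank_range = c(250, 3000)) {
  if (central_halfwidth > flank_range[1]) {
    abort("central window must not extend past flank_range[1]")
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    abort("profiles must be a named list")
  }
  imap(profiles, function(sm, sample) {
    stopifnot(inherits(sm, "signal_matrix"))
    if (sm$flank < flank_range[2]) {
      abort("profile flank smaller than flank_range")
    }
    mid <- sm$offsets + sm$bin / 2   # bin midpoints, offset from center
    prof <- sm$mean_profile
    if (!is.null(scale_factors)) prof <- prof * scale_factors[[sample]]
    central_idx <- abs(mid) <= central_halfwidth
    flank_idx <- abs(mid) > flank_range[1] & abs(mid) <= flank_range[2]
    tibble(sample = sample,
           central = mean(prof[central_idx]),
           flank = mean(prof[flank_idx]))
  }) |> list_rbind()
}

#' Genotype contrast of a central/flank decomposition
#'
#' @param decomp Output of [central_flank_decomposition()].
#' @param numerator,denominator Sample names.
#' @return One-row tibble: `central_ratio`, `flank_ratio`.
#' @export
genotype_contrast <- function(decomp, numerator, denominator) {
  a <- decomp[decomp$sample == numerator, ]
  b <- decomp[decomp$sample == denominator, ]
  if (nrow(a) != 1L || nrow(b) != 1L) abort("sample names not found")
  tibble(central_ratio = a$central / b$central,
         flank_ratio = a$flank / b$flank)
}

#' Spearman correlation between per-hotspot strength metrics
#'
#' Rank correlation between two per-hotspot columns, after an optional
#' restriction (e.g. autosomal hotspots coinciding with a called peak).
#' Ties get average ranks; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param tbl Tibble of per-hotspot metrics.
#' @param x,y Column names (strings) of the two metrics.
#' @param restrict Optional logical vector (length `nrow(tbl)`) selecting
#'   the hotspots to use.
#' @param min_n Minimum hotspots after restriction (default 10).
#' @return One-row tibble: `metric_x`, `metric_y`, `rho`, `p`, `n`.
#' @export
strength_correlation <- function(tbl, x, y, restrict = NULL, min_n = 10) {
  if (!is.null(restrict)) tbl <- tbl[restrict, ]
  if (nrow(tbl) < min_n) {
    abort(sprintf("need at least %d hotspots after restriction", min_n))
  }
  r <- spearman_cor(tbl[[x]], tbl[[y]], p_method = "t")
  tibble(metric_x = x, metric_y = y, rho = r$rho, p = r$p, n = r$n)
}
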