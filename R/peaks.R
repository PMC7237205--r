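#' Poisson window enrichment peak caller
#'
#' A deliberately simple, fully documented stand-in for general-purpose
#' peak callers: each bin of a raw-count track is tested against a Poisson
#' background rate, significant bins closer than `merge_gap` are merged into
#' peaks, and peaks are annotated with a summit and fold enrichment.
#' Externally called peak BED files can always be substituted downstream via
#' [read_bed()].
#'
#' The background rate for a bin is
#' `lambda = max(global mean, depth-scaled control mean)` where the control
#' track (if given) is scaled by the signal/control depth ratio and the
#' control mean is taken as the larger of the control bin itself and a
#' running mean over `lambda_window` bp around it (the per-bin value
#' suppresses sharp shared artefacts; the running mean guards against
#' downward noise in single control bins). With `local_lambda = "global"`
#' only the global mean is used. A bin with count `x` is significant iff
#' the Poisson upper tail `P(X >= x | lambda)` is at most `p_max`. No
#' deduplication is performed anywhere in this module.
#'
#' @param signal A `binned_track` of raw counts.
#' @param control Optional `binned_track` of raw counts, same binning.
#' @param p_max Per-bin Poisson p-value threshold (default 0.001).
#' @param merge_gap Maximum gap in bp between significant bins merged into
#'   one peak (default 500; use ~1000 for END-seq-style broad signal).
#' @param fold_min Peaks with fold enrichment `<= fold_min` are dropped
#'   (default 0, i.e. keep all; 2.5 reproduces the END-seq retention rule
#'   "fold enrichment > 2.5").
#' @param local_lambda `"global"` or `"control-scaled"`.
#' @param lambda_window Width in bp of the running-mean window applied to
#'   the control track (default 1000).
#' @return Tibble of peaks: `chrom`, `start`, `end`, `summit`, `fold`, `p`
#'   (minimum bin p-value), with the calling parameters in attribute
#'   `params`. Peaks are non-overlapping.
#' @export
call_peaks <- function(signal, control = NULL, p_max = 0.001,
                       merge_gap = 500, fold_min = 0,
                       local_lambda = c("global", "control-scaled"),
                       lambda_window = 1000) {
  local_lambda <- match.arg(local_lambda)
  stopifnot(inherits(signal, "binned_track"))
  if (!is.null(control)) {
    stopifnot(inherits(control, "binned_track"), control$bin == signal$bin)
  }
  bin <- signal$bin
  total_signal <- sum(vapply(signal$values, sum, 0))
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  summit = numeric(), fold = numeric(), p = numeric())
  params <- list(p_max = p_max, merge_gap = merge_gap, fold_min = fold_min,
                 local_lambda = local_lambda, bin = bin)
  if (total_signal == 0) {
    attr(empty, "params") <- params
    return(empty)
  }
  n_bins_total <- sum(vapply(signal$values, length, 0L))
  lambda_global <- total_signal / n_bins_total
  depth_ratio <- if (!is.null(control)) {
    total_control <- sum(vapply(control$values, sum, 0))
    if (total_control == 0) abort("control track has zero total")
    total_signal / total_control
  } else NA_real_

  peaks <- imap(signal$values, function(v, chrom_name) {
    lam <- rep(lambda_global, length(v))
    if (local_lambda == "control-scaled" && !is.null(control)) {
      cv <- control$values[[chrom_name]]
      lam <- pmax(lam, cv * depth_ratio,
                  running_mean(cv, max(1L, round(lambda_window / bin))) *
                    depth_ratio)
    }
    p <- ppois(v - 1, lam, lower.tail = FALSE)
    sig <- which(p <= p_max)
    if (!length(sig)) return(NULL)
    gap_bins <- floor(merge_gap / bin)
    grp <- cumsum(c(1, diff(sig) > gap_bins + 1))
    chrom_len <- signal$genome[[chrom_name]]
    map(split(sig, grp), function(idx) {
      span <- seq(min(idx), max(idx))
      imax <- span[which.max(v[span])]
      tibble(chrom = chrom_name,
             start = (min(idx) - 1) * bin,
             end = min(max(idx) * bin, chrom_len),
             summit = floor(((imax - 1) * bin + imax * bin) / 2),
             fold = v[imax] / lam[imax],
             p = min(p[idx]))
    }) |> list_rbind()
  }) |> list_rbind()

  if (is.null(peaks) || nrow(peaks) == 0L) peaks <- empty
  peaks <- peaks[peaks$fold > fold_min, ]
  peaks <- arrange(peaks, .data$chrom, .data$start)
  attr(peaks, "params") <- params
  peaks
}

# centered running mean with shrinking windows at the edges
running_mean <- function(v, w) {
  if (w <= 1L) return(v)
  half <- floor(w / 2)
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Per-interval fragment counts (peak strength)
#'
#' Hotspot or peak strength as the sum of in-peak sequencing fragments: a
#' fragment counts for an interval iff it overlaps it by at least 1 bp.
#'
#' @param intervals Interval tibble (peaks or hotspots).
#' @param fragments Fragment tibble.
#' @return `intervals` with an added `strength` column.
#' @export
peak_strength <- function(intervals, fragments) {
  check_intervals(intervals)
  cnt <- if (nrow(fragments)) {
    GenomicRanges::countOverlaps(as_granges0(intervals),
                                 as_granges0(fragments))
  } else rep(0L, nrow(intervals))
  mutate(intervals, strength = as.numeric(cnt))
}
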