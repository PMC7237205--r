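#' Load sequenced fragments from BEDPE or SAM/BAM alignments
#'
#' A fragment is the outer span of a properly paired read pair,
#' `[min(start), max(end))` in 0-based half-open coordinates. BEDPE input is
#' assumed to carry already-filtered templates: each record contributes the
#' outer span of its two blocks. SAM/BAM input is resolved per template:
#' pairs whose mates map to different chromosomes are skipped (a count is
#' attached as attribute `n_discordant`), and templates with mapping quality
#' not strictly greater than `min_mapq` are dropped — a MAPQ of exactly
#' `min_mapq` is removed.
#'
#' @param path Path to a BEDPE file, or a SAM/BAM file (requires Rsamtools).
#' @param format `"bedpe"`, `"sam"` or `"bam"`.
#' @param min_mapq Mapping-quality cutoff; templates kept iff
#'   `mapq > min_mapq` (default 30). Ignored for BEDPE.
#' @return Fragment tibble with columns `chrom`, `start`, `end`, `length`.
#' @export
load_fragments <- function(path, format = c("bedpe", "sam", "bam"),
                           min_mapq = 30) {
  format <- match.arg(format)
  if (format == "bedpe") {
    x <- tryCatch(
      readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                      comment = "#", progress = FALSE),
      error = function(e) NULL)
    if (is.null(x) || nrow(x) == 0L) {
      return(tibble(chrom = character(), start = numeric(),
                    end = numeric(), length = numeric()))
    }
    if (ncol(x) < 6L) abort("BEDPE needs 6 columns")
    disc <- as.character(x[[1]]) != as.character(x[[4]])
    if (any(disc)) {
      warn(sprintf("skipped %d discordant pairs", sum(disc)))
      x <- x[!disc, ]
    }
    frags <- tibble(
      chrom = as.character(x[[1]]),
      start = pmin(as.numeric(x[[2]]), as.numeric(x[[5]])),
      end = pmax(as.numeric(x[[3]]), as.numeric(x[[6]]))
    )
    attr(frags, "n_discordant") <- sum(disc)
  } else {
    frags <- load_fragments_sam(path, format, min_mapq)
  }
  frags$length <- frags$end - frags$start
  check_intervals(frags, what = "fragments")
  frags
}

load_fragments_sam <- function(path, format, min_mapq) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("SAM/BAM input requires the Rsamtools package")
  }
  if (format == "sam") {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "isize"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  d <- tibble(qname = b$qname, chrom = as.character(b$rname),
              pos = b$pos, mapq = b$mapq, isize = b$isize)
  d <- d[!is.na(d$pos), ]
  per <- d |>
    group_by(.data$qname) |>
    summarise(nchrom = length(unique(.data$chrom)),
              chrom = .data$chrom[1],
              start = min(.data$pos) - 1,  # SAM is 1-based
              span = max(abs(.data$isize), na.rm = TRUE),
              mapq = min(.data$mapq), .groups = "drop")
  disc <- per$nchrom > 1L
  if (any(disc)) warn(sprintf("skipped %d discordant pairs", sum(disc)))
  per <- per[!disc & per$mapq > min_mapq & per$span > 0, ]
  out <- tibble(chrom = per$chrom, start = per$start,
                end = per$start + per$span)
  attr(out, "n_discordant") <- sum(disc)
  out
}

#' Filter fragments by length
#'
#' Retains fragments with `lo <= length <= hi` (closed range on both ends).
#' The default window 130-200 bp selects the mono-nucleosome-protected
#' CUT&RUN fragments used for coverage profiles.
#'
#' @param fragments Fragment tibble.
#' @param lo,hi Inclusive length bounds in bp.
#' @return Filtered fragment tibble; attribute `retained_fraction` records
#'   the surviving proportion.
#' @export
filter_fragment_length <- function(fragments, lo = 130, hi = 200) {
  stopifnot(lo <= hi)
  len <- fragments$end - fragments$start
  keep <- len >= lo & len <= hi
  out <- fragments[keep, ]
  attr(out, "retained_fraction") <-
    if (nrow(fragments)) mean(keep) else NA_real_
  out
}

# Central three bases of a fragment: c = floor((start + end - 1) / 2),
# window {c-1, c, c+1}, as 0-based base positions.
fragment_center_bases <- function(fragments) {
  ctr <- floor((fragments$start + fragments$end - 1) / 2)
  tibble(
    chrom = rep(fragments$chrom, each = 3L),
    pos = as.vector(rbind(ctr - 1, ctr, ctr + 1))
  )
}

new_binned_track <- function(values, genome, bin, normalization = "raw") {
  structure(list(values = values, genome = genome, bin = bin,
                 normalization = normalization),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %d chrom(s), %d bp bins, %s\n",
              length(x$values), x$bin, x$normalization))
  cat(sprintf("  total mass: %g\n", sum(vapply(x$values, sum, 0))))
  invisible(x)
}

#' Convert a binned track to a tidy bedGraph-style tibble
#'
#' @param x A `binned_track`.
#' @param drop_zero Drop zero bins (default TRUE, bedGraph style).
#' @param ... Unused.
#' @return Tibble with `chrom`, `start`, `end`, `score`.
#' @method as_tibble binned_track
#' @export
as_tibble.binned_track <- function(x, drop_zero = TRUE, ...) {
  out <- imap(x$values, function(v, chrom_name) {
    idx <- if (drop_zero) which(v != 0) else seq_along(v)
    chrom_len <- x$genome[[chrom_name]]
    tibble(chrom = chrom_name,
           start = (idx - 1) * x$bin,
           end = pmin(idx * x$bin, chrom_len),
           score = v[idx])
  }) |> list_rbind()
  out
}

#' Write a binned track as bedGraph
#'
#' @param x A `binned_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  out <- as_tibble.binned_track(x, drop_zero = TRUE)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Fragment-center-weighted binned coverage
#'
#' Implements the trimmed-fragment coverage used for CUT&RUN profiles: only
#' the central three nucleotides of each fragment are counted, into
#' genome-anchored bins of `bin` bp (bin k covers `[k*bin, (k+1)*bin)`).
#' For a fragment `[start, end)` the center base is
#' `c = floor((start + end - 1) / 2)` and bases `c-1, c, c+1` each add one
#' unit of mass to their containing bin, so the three units may split across
#' two adjacent bins. Total track mass equals 3 x fragment count except for
#' center bases clipped at chromosome edges.
#'
#' @param fragments Fragment tibble.
#' @param genome Genome declaration (named vector chrom -> length).
#' @param bin Bin width in bp (default 50).
#' @return A `binned_track` with raw counts.
#' @export
center_weighted_coverage <- function(fragments, genome, bin = 50) {
  genome <- check_genome(genome)
  bases <- fragment_center_bases(fragments)
  values <- lapply(names(genome), function(chrom) {
    n_bins <- ceiling(genome[[chrom]] / bin)
    p <- bases$pos[bases$chrom == chrom]
    p <- p[p >= 0 & p < genome[[chrom]]]
    if (!length(p)) return(numeric(n_bins))
    as.numeric(tabulate(floor(p / bin) + 1L, nbins = n_bins))
  })
  new_binned_track(setNames(values, names(genome)), genome, bin)
}

#' Bin 5'-end read positions into a coverage track
#'
#' @param reads Tibble with columns `chrom`, `pos` (0-based 5' ends).
#' @param genome Genome declaration.
#' @param bin Bin width in bp (default 50).
#' @return A `binned_track` of read counts.
#' @export
read_coverage <- function(reads, genome, bin = 50) {
  genome <- check_genome(genome)
  values <- lapply(names(genome), function(chrom) {
    n_bins <- ceiling(genome[[chrom]] / bin)
    p <- reads$pos[reads$chrom == chrom]
    p <- p[p >= 0 & p < genome[[chrom]]]
    if (!length(p)) return(numeric(n_bins))
    as.numeric(tabulate(floor(p / bin) + 1L, nbins = n_bins))
  })
  new_binned_track(setNames(values, names(genome)), genome, bin)
}

#' Reads-per-million normalization of a binned track
#'
#' @param track A `binned_track`.
#' @param total_fragments Library size used as the denominator.
#' @return The track with values scaled by `1e6 / total_fragments`.
#' @export
rpm_normalize <- function(track, total_fragments) {
  stopifnot(inherits(track, "binned_track"))
  if (total_fragments <= 0) abort("total_fragments must be positive")
  track$values <- lapply(track$values, function(v) v * 1e6 / total_fragments)
  track$normalization <- "RPM"
  track
}

#' Windowed RPKM of 5'-end reads
#'
#' `RPKM_w = count_w * 1e9 / (total_reads * width_w)` where a read counts
#' for window `w` iff its 5' end lies in `[start, end)`.
#'
#' @param reads Tibble with columns `chrom`, `pos` (0-based 5' ends).
#' @param windows Interval tibble.
#' @param total_reads Library size; defaults to `nrow(reads)`.
#' @return `windows` with added columns `count` and `rpkm`.
#' @export
window_rpkm <- function(reads, windows, total_reads = nrow(reads)) {
  check_intervals(windows, what = "windows")
  if (nrow(windows) == 0L) abort("windows must be non-empty")
  if (total_reads <= 0) abort("total_reads must be positive")
  gp <- GenomicRanges::GRanges(as.character(reads$chrom),
                               IRanges::IRanges(reads$pos + 1L, width = 1L))
  cnt <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(windows), gp))
  windows |>
    mutate(count = as.numeric(cnt),
           rpkm = .data$count * 1e9 /
             (total_reads * (.data$end - .data$start)))
}
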