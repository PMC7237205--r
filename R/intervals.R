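#' Read a BED file into an interval tibble
#'
#' Intervals are kept in BED convention throughout: 0-based, half-open
#' `[start, end)`. BED3 yields columns `chrom`, `start`, `end`; BED6 adds
#' `name`, `score`, `strand`.
#'
#' @param path Path to a tab-delimited BED3 or BED6 file.
#' @param genome Optional genome declaration (named vector chrom -> length);
#'   when given, intervals on unknown chromosomes raise an error unless
#'   `skip_unknown = TRUE`, in which case they are dropped with a warning.
#' @param skip_unknown Drop (rather than error on) intervals whose chromosome
#'   is absent from `genome`.
#' @return A tibble of intervals sorted by (chrom, start).
#' @export
read_bed <- function(path, genome = NULL, skip_unknown = FALSE) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       comment = "#", progress = FALSE)
  if (ncol(x) < 3L) abort("BED file needs at least 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6L))]
  x <- x[, seq_len(min(ncol(x), 6L))]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf("line %d: start >= end (%s:%g-%g)", bad,
                  x$chrom[bad], x$start[bad], x$end[bad]))
  }
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    unknown <- !(x$chrom %in% names(genome))
    if (any(unknown)) {
      if (!skip_unknown) {
        abort(paste0("unknown chromosome in BED: ", unique(x$chrom[unknown])[1]))
      }
      warn(sprintf("dropped %d intervals on undeclared chromosomes",
                   sum(unknown)))
      x <- x[!unknown, ]
    }
  }
  check_intervals(x, genome)
  as_tibble(x) |> arrange(.data$chrom, .data$start)
}

#' Write an interval tibble as BED
#'
#' Writes BED3 or, when `name`/`score`/`strand` columns are present, BED6.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, "name", "score", "strand")
  }
  out <- x[, cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge nearby anchor points and recenter each cluster
#'
#' Single-linkage chaining: anchors at distance `<= radius` on the same
#' chromosome join one cluster, and each cluster is replaced by a single
#' anchor at the (floored) midpoint of its extreme positions. This mirrors
#' the merge-and-recenter step applied to transcription start/end sites
#' before profile plotting. Clustering is strand-blind; the output anchor
#' keeps the strand of the first member of its cluster.
#'
#' @param anchors Tibble with columns `chrom`, `pos` (0-based point) and
#'   optionally `strand`.
#' @param radius Maximum merge distance in bp (default 500).
#' @return Anchor tibble; output anchors on one chromosome are pairwise more
#'   than `radius` apart, so the operation is idempotent.
#' @export
merge_cluster_recenter <- function(anchors, radius = 500) {
  stopifnot(radius >= 0)
  if (!all(c("chrom", "pos") %in% names(anchors))) {
    abort("anchors must have columns chrom, pos")
  }
  if (nrow(anchors) == 0L) return(as_tibble(anchors))
  if (!"strand" %in% names(anchors)) anchors$strand <- "."
  anchors |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(cluster = cumsum(c(1, diff(.data$pos) > radius))) |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(
      strand = .data$strand[1],
      pos = floor((min(.data$pos) + max(.data$pos)) / 2),
      .groups = "drop"
    ) |>
    select("chrom", "pos", "strand") |>
    arrange(.data$chrom, .data$pos)
}

#' Remove intervals overlapping a blacklist
#'
#' Any query interval overlapping a blacklist region by at least 1 bp is
#' dropped entirely (no trimming), matching the usual treatment of
#' artefact-prone regions before peak reporting.
#'
#' @param x Interval tibble.
#' @param blacklist Interval tibble of regions to exclude.
#' @return `x` without blacklisted rows.
#' @export
subtract_blacklist <- function(x, blacklist) {
  check_intervals(x); check_intervals(blacklist, what = "blacklist")
  if (nrow(x) == 0L || nrow(blacklist) == 0L) return(x)
  hits <- GenomicRanges::countOverlaps(as_granges0(x), as_granges0(blacklist))
  x[hits == 0L, ]
}

#' Tabulate membership of query intervals in named reference sets
#'
#' For every query interval and every named reference set, reports whether
#' the query overlaps at least `min_bp` bases of some reference interval —
#' the information behind upset plots of peak intersections.
#'
#' @param query Interval tibble.
#' @param refs Named list of interval tibbles.
#' @param min_bp Minimum overlap in bp to count as membership (default 1).
#' @return The query tibble with one logical column per reference set.
#'   Attributes `fractions` (per-reference fraction of queries overlapping)
#'   and `combination_counts` (tibble of counts per membership pattern,
#'   which partition the query set) summarise the table; see
#'   [membership_summary()].
#' @export
interval_membership <- function(query, refs, min_bp = 1) {
  check_intervals(query, what = "query")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    abort("refs must be a named list of interval tibbles")
  }
  gq <- as_granges0(query)
  out <- as_tibble(query)
  for (nm in names(refs)) {
    check_intervals(refs[[nm]], what = nm)
    out[[nm]] <- GenomicRanges::countOverlaps(
      gq, as_granges0(refs[[nm]]), minoverlap = min_bp) > 0L
  }
  memb <- out[, names(refs), drop = FALSE]
  fractions <- vapply(memb, mean, numeric(1))
  combo <- memb |>
    group_by(across(all_of(names(refs)))) |>
    summarise(n = n(), .groups = "drop") |>
    arrange(desc(.data$n))
  attr(out, "fractions") <- fractions
  attr(out, "combination_counts") <- combo
  out
}

#' Summarise a membership table
#'
#' @param x Result of [interval_membership()].
#' @return List with `fractions` and `combination_counts`.
#' @export
membership_summary <- function(x) {
  list(fractions = attr(x, "fractions"),
       combination_counts = attr(x, "combination_counts"))
}
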