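#' Anchor-centered signal matrix
#'
#' Builds the matrix behind motif-centered heatmaps and mean-profile plots:
#' one row per anchor, one column per offset bin covering
#' `[-flank, +flank)` around the anchor position. Signal can be supplied as
#' a fragment tibble (each fragment contributes its three central bases, as
#' in [center_weighted_coverage()]), a 5'-end read tibble with columns
#' `chrom`, `pos` (each read contributes one unit), or a `binned_track`
#' (each bin contributes its mass at the bin midpoint).
#'
#' Minus-strand anchors have their columns reversed so that profiles read
#' in motif orientation. Anchors within `flank` of a chromosome edge are
#' dropped with a warning.
#'
#' @param x Fragment tibble, read tibble, or `binned_track`.
#' @param anchors Anchor tibble with columns `chrom`, `pos` and optionally
#'   `strand`.
#' @param flank Half-window in bp; must be a multiple of `bin`.
#' @param bin Offset bin width in bp (default 50).
#' @param genome Genome declaration (named vector), required for the edge
#'   filter unless `x` is a `binned_track`.
#' @param flip_minus_strand Reverse columns of minus-strand anchors
#'   (default TRUE).
#' @param row_order `"descending_row_sum"` (default) or `"input"`.
#' @return A `signal_matrix`: list with `matrix` (anchors x bins),
#'   `offsets` (bin start offsets), `mean_profile`, `anchors` (retained),
#'   `bin`, `flank`.
#' @export
anchor_profile <- function(x, anchors, flank, bin = 50, genome = NULL,
                           flip_minus_strand = TRUE,
                           row_order = c("descending_row_sum", "input")) {
  row_order <- match.arg(row_order)
  if (flank %% bin != 0) abort("flank must be a multiple of bin")
  if (!all(c("chrom", "pos") %in% names(anchors))) {
    abort("anchors need columns chrom, pos")
  }
  if (!"strand" %in% names(anchors)) anchors$strand <- "."
  if (inherits(x, "binned_track")) {
    genome <- x$genome
    pts <- as_tibble.binned_track(x, drop_zero = TRUE)
    pts <- tibble(chrom = pts$chrom,
                  pos = floor((pts$start + pts$end) / 2),
                  w = pts$score)
  } else if (all(c("chrom", "start", "end") %in% names(x))) {
    b <- fragment_center_bases(x)
    pts <- tibble(chrom = b$chrom, pos = b$pos, w = 1)
  } else if (all(c("chrom", "pos") %in% names(x))) {
    pts <- tibble(chrom = x$chrom, pos = x$pos, w = 1)
  } else {
    abort("x must be fragments, reads (chrom/pos) or a binned_track")
  }
  if (is.null(genome)) abort("genome declaration required")
  genome <- check_genome(genome)

  ok <- anchors$pos - flank >= 0 &
    anchors$pos + flank <= genome[anchors$chrom]
  if (!any(ok)) abort("no anchors survive the chromosome-edge filter")
  if (any(!ok)) {
    warn(sprintf("dropped %d anchors within %d bp of a chromosome edge",
                 sum(!ok), flank))
  }
  anchors <- anchors[ok, ]
  n <- nrow(anchors)
  ncol_ <- as.integer(2 * flank / bin)

  m <- matrix(0, nrow = n, ncol = ncol_)
  for (chrom in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chrom)
    pi <- which(pts$chrom == chrom)
    if (!length(pi)) next
    win <- IRanges::IRanges(start = anchors$pos[ai] - flank + 1L,
                            width = 2L * flank)
    pr <- IRanges::IRanges(start = pts$pos[pi] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(pr, win)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    off <- pts$pos[pi][qi] - (anchors$pos[ai][si] - flank)
    col <- floor(off / bin) + 1L
    row <- ai[si]
    flat <- (col - 1L) * n + row
    add <- rowsum(pts$w[pi][qi], group = flat)
    m[as.integer(rownames(add))] <- m[as.integer(rownames(add))] + add[, 1]
  }
  if (flip_minus_strand) {
    neg <- which(anchors$strand == "-")
    if (length(neg)) m[neg, ] <- m[neg, ncol_:1, drop = FALSE]
  }
  if (row_order == "descending_row_sum") {
    ord <- order(rowSums(m), decreasing = TRUE)
    m <- m[ord, , drop = FALSE]
    anchors <- anchors[ord, ]
  }
  structure(list(matrix = m,
                 offsets = seq(-flank, flank - bin, by = bin),
                 mean_profile = colMeans(m),
                 anchors = anchors, bin = bin, flank = flank),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d anchors x %d bins (%d bp, flank %d bp)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin, x$flank))
  invisible(x)
}

#' Tidy a signal matrix into long format
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return Tibble with `anchor` (row index), `offset` (bin start, bp),
#'   `signal`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  tibble(anchor = rep(seq_len(nrow(x$matrix)), times = ncol(x$matrix)),
         offset = rep(x$offsets, each = nrow(x$matrix)),
         signal = as.vector(x$matrix))
}

#' Mean-profile and heatmap plot of a signal matrix
#'
#' @param object A `signal_matrix`.
#' @param ... Unused.
#' @return A ggplot showing the mean signal per offset bin.
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, ...) {
  df <- tibble(offset = object$offsets + object$bin / 2,
               signal = object$mean_profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from anchor (bp)",
                  y = sprintf("mean signal / %d bp", object$bin)) +
    ggplot2::theme_minimal()
}
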