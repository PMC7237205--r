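#' Build a position weight matrix
#'
#' Accepts an L x 4 matrix of base counts or probabilities (columns A, C,
#' G, T). A pseudocount is added per base and rows renormalized; log-odds
#' are `log2(p / background)`.
#'
#' @param x L x 4 numeric matrix (counts or probabilities), columns in
#'   order A, C, G, T.
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param pseudocount Added to every cell before renormalization
#'   (default 0.01).
#' @return A `pwm` object: list with `prob`, `log_odds`, `background`,
#'   `length`.
#' @export
pwm <- function(x, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.01) {
  x <- as.matrix(x)
  if (ncol(x) != 4L) abort("PWM must have 4 columns (A, C, G, T)")
  if (nrow(x) < 4L) abort("PWM must be at least 4 positions long")
  if (any(x < 0)) abort("PWM entries must be non-negative")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    abort("background must be positive frequencies summing to 1")
  }
  p <- x + pseudocount
  p <- p / rowSums(p)
  colnames(p) <- c("A", "C", "G", "T")
  lo <- sweep(log2(p), 2, log2(background), "-")
  structure(list(prob = p, log_odds = lo,
                 background = setNames(background, c("A", "C", "G", "T")),
                 length = nrow(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> length %d, consensus %s\n", x$length, pwm_consensus(x)))
  invisible(x)
}

#' Read a PWM from a 4-column tab-delimited file
#'
#' Expects a header line `A C G T` and one row per motif position, holding
#' counts or probabilities.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
read_pwm <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                     pseudocount = 0.01) {
  x <- readr::read_tsv(path, col_types = "dddd", progress = FALSE)
  pwm(as.matrix(x[, c("A", "C", "G", "T")]), background, pseudocount)
}

#' Write a PWM's probability matrix as TSV
#' @param x A `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  readr::write_tsv(as_tibble(x$prob), path, progress = FALSE)
  invisible(path)
}

#' Build a sharply peaked PWM from a consensus sequence
#'
#' Each position puts all count mass on the consensus base; softness enters
#' only through the pseudocount.
#'
#' @param consensus A/C/G/T string.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(consensus,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               pseudocount = 0.01) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) abort("consensus must be ACGT")
  m <- matrix(0, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 1
  pwm(m, background, pseudocount)
}

#' Consensus string of a PWM
#' @param x A `pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$prob, 1, which.max)], collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Log-odds score of a pwm at every start of an integer-coded sequence
# (A=1..T=4; other codes give -Inf). Returns numeric of length n - L + 1.
score_positions <- function(codes, lo) {
  L <- nrow(lo)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1L)]
    v <- unname(lo[j, cj])
    v[is.na(cj)] <- -Inf
    sc <- sc + v
  }
  sc
}

seq_to_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

#' Scan a genome with a PWM on both strands
#'
#' Scores every position on the forward strand with the PWM and on the
#' reverse strand with its reverse complement (equivalently, scanning the
#' reverse-complemented sequence). Hits at or above `threshold` are
#' reported; overlapping hits are resolved greedily best-score-first, with
#' ties broken leftmost-first then plus-strand-first.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `synthetic_genome`.
#' @param pwm A `pwm`.
#' @param threshold Minimum log-odds score (finite).
#' @param resolve_overlaps Apply greedy overlap resolution (default TRUE).
#' @return Tibble of hits: `chrom`, `start` (0-based), `strand`, `score`.
#' @export
scan_motif <- function(genome, pwm, threshold, resolve_overlaps = TRUE) {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold))
  seqs <- genome_sequences(genome)
  L <- pwm$length
  # reverse-strand log-odds: reverse positions, swap complementary bases
  lo_f <- pwm$log_odds
  lo_r <- lo_f[L:1, c("T", "G", "C", "A"), drop = FALSE]
  hits <- imap(seqs, function(s, chrom) {
    codes <- seq_to_codes(s)
    if (length(codes) < L) abort("sequence shorter than motif")
    sf <- score_positions(codes, lo_f)
    sr <- score_positions(codes, lo_r)
    kf <- which(sf >= threshold); kr <- which(sr >= threshold)
    tibble(chrom = chrom,
           start = c(kf, kr) - 1,
           strand = c(rep("+", length(kf)), rep("-", length(kr))),
           score = c(sf[kf], sr[kr]))
  }) |> list_rbind()
  if (resolve_overlaps && nrow(hits) > 1L) {
    hits <- hits |>
      arrange(desc(.data$score), .data$start,
              factor(.data$strand, levels = c("+", "-"))) |>
      group_by(.data$chrom) |>
      group_modify(function(d, key) {
        keep <- logical(nrow(d))
        taken_start <- numeric(0)
        for (i in seq_len(nrow(d))) {
          if (!length(taken_start) ||
              all(abs(d$start[i] - taken_start) >= L)) {
            keep[i] <- TRUE
            taken_start <- c(taken_start, d$start[i])
          }
        }
        d[keep, ]
      }) |>
      ungroup()
  }
  hits |>
    mutate(width = L) |>
    arrange(.data$chrom, .data$start)
}

#' Center hotspots on unique motif hits
#'
#' Hotspots containing exactly one motif hit become anchors at the motif
#' midpoint `floor((motif_start + motif_end) / 2)` with the motif's strand.
#' Hotspots with zero hits cannot be motif-centered and hotspots with two
#' or more hits are excluded (multi-motif exclusion); both are counted in
#' the attached exclusion report.
#'
#' @param hotspots Interval tibble.
#' @param hits Motif-hit tibble from [scan_motif()] (columns `chrom`,
#'   `start`, `strand`, `score`, `width`).
#' @return Anchor tibble (`chrom`, `pos`, `strand`, plus hotspot
#'   coordinates) with attribute `exclusions` = list(n_zero, n_multi,
#'   n_centered).
#' @export
center_and_filter_hotspots <- function(hotspots, hits) {
  check_intervals(hotspots, what = "hotspots")
  gh <- as_granges0(hotspots)
  gm <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L,
                                                width = hits$width))
  ov <- GenomicRanges::findOverlaps(gh, gm)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nhits <- tabulate(qh, nbins = nrow(hotspots))
  single <- which(nhits == 1L)
  hit_idx <- sh[match(single, qh)]
  anchors <- tibble(
    chrom = hotspots$chrom[single],
    pos = floor((hits$start[hit_idx] +
                   hits$start[hit_idx] + hits$width[hit_idx]) / 2),
    strand = hits$strand[hit_idx],
    hotspot_start = hotspots$start[single],
    hotspot_end = hotspots$end[single],
    motif_score = hits$score[hit_idx]
  )
  attr(anchors, "exclusions") <- list(
    n_zero = sum(nhits == 0L),
    n_multi = sum(nhits >= 2L),
    n_centered = length(single)
  )
  anchors
}

#' Assign a PRDM9 allele to each hotspot by competitive PWM scoring
#'
#' For every hotspot interval the best log-odds score of each allele's PWM
#' (both strands, all in-hotspot offsets) is computed; the hotspot is
#' labeled with the higher-scoring allele, or `"ambiguous"` when the score
#' difference is below `margin`.
#'
#' @param hotspots Interval tibble.
#' @param genome Named character vector of sequences (or
#'   `synthetic_genome`).
#' @param pwm_a,pwm_b `pwm` objects for the two alleles.
#' @param labels Length-2 character labels (default `c("Dom2", "Cast")`).
#' @param margin Minimum score difference in bits to call an allele
#'   (default 1).
#' @return `hotspots` with added columns `score_a`, `score_b`, `allele`.
#' @export
assign_allele_by_motif <- function(hotspots, genome, pwm_a, pwm_b,
                                   labels = c("Dom2", "Cast"), margin = 1) {
  check_intervals(hotspots, what = "hotspots")
  seqs <- genome_sequences(genome)
  best <- function(p) {
    vapply(seq_len(nrow(hotspots)), function(i) {
      s <- substr(seqs[[hotspots$chrom[i]]],
                  hotspots$start[i] + 1L, hotspots$end[i])
      codes <- seq_to_codes(s)
      if (length(codes) < p$length) return(-Inf)
      lo_r <- p$log_odds[p$length:1, c("T", "G", "C", "A"), drop = FALSE]
      max(score_positions(codes, p$log_odds),
          score_positions(codes, lo_r))
    }, numeric(1))
  }
  sa <- best(pwm_a); sb <- best(pwm_b)
  hotspots |>
    mutate(score_a = sa, score_b = sb,
           allele = case_when(
             abs(sa - sb) < margin ~ "ambiguous",
             sa > sb ~ labels[1],
             TRUE ~ labels[2]
           ))
}
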