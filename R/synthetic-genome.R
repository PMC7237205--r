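#' Generate a random synthetic genome
#'
#' Uniform random A/C/G/T sequence per chromosome, reproducible by seed.
#' Used as the substrate into which hotspot motifs are planted.
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   each at least 10 kb.
#' @return A `synthetic_genome`: list with `lengths`, `sequences`, `seed`.
#' @export
generate_genome <- function(seed, chrom_lengths) {
  chrom_lengths <- check_genome(chrom_lengths)
  if (any(chrom_lengths < 1e4)) abort("chromosome lengths must be >= 10 kb")
  local_seed_if(seed)
  sequences <- lapply(chrom_lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
  structure(list(lengths = chrom_lengths,
                 sequences = setNames(sequences, names(chrom_lengths)),
                 seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chrom(s), %g bp total (seed %s)\n",
              length(x$lengths), sum(x$lengths), x$seed))
  invisible(x)
}

# Named character vector of sequences from a synthetic_genome or a plain
# named character vector.
genome_sequences <- function(genome) {
  if (inherits(genome, "synthetic_genome")) {
    return(vapply(genome$sequences, identity, character(1)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("genome must be a synthetic_genome or named character vector")
}

#' Genome declaration (chrom -> length) of a genome object
#' @param genome A `synthetic_genome` or named character vector of
#'   sequences.
#' @return Named numeric vector of lengths.
#' @export
genome_lengths <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$lengths)
  if (is.numeric(genome)) return(check_genome(genome))
  setNames(nchar(genome_sequences(genome)), names(genome))
}

#' Write genome sequences as FASTA
#' @param genome A `synthetic_genome` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  s <- genome_sequences(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path)
  invisible(path)
}

splice_sequence <- function(seq, start0, replacement) {
  # start0 is a 0-based position; replacement overwrites in place
  paste0(substr(seq, 1, start0),
         replacement,
         substr(seq, start0 + nchar(replacement) + 1, nchar(seq)))
}

#' Plant motif-anchored hotspots into a synthetic genome
#'
#' Chooses `n` hotspot centers (pairwise at least `min_spacing` apart and
#' away from chromosome edges), assigns each an allele label drawn from
#' `allele_mix`, a strand, and a lognormal relative strength, and writes
#' the allele's consensus motif into the sequence centered on the hotspot
#' center (reverse-complemented for minus-strand hotspots). A fixed
#' fraction of hotspots receives a second motif copy 300 bp downstream to
#' exercise multi-motif exclusion in downstream centering.
#'
#' @param genome A `synthetic_genome`.
#' @param n Number of hotspots.
#' @param motifs Named character vector of allele consensus motifs, e.g.
#'   `c(Dom2 = "...", Cast = "...")`.
#' @param allele_mix Named numeric vector of allele probabilities summing
#'   to 1 (names must match `motifs`); default equal mix.
#' @param min_spacing Minimum distance between hotspot centers (bp,
#'   default 10000); must exceed the motif length.
#' @param multi_motif_fraction Fraction of hotspots given two motif copies
#'   (default 0).
#' @param edge_margin Minimum distance of a center from a chromosome end
#'   (bp, default 5000).
#' @param strength_sdlog sdlog of the lognormal relative strengths
#'   (default 1).
#' @param seed Optional seed.
#' @return List with `genome` (motifs planted) and `truth`, a tibble with
#'   one row per hotspot: `chrom`, `center`, `allele`, `strand`,
#'   `strength`, `n_motifs`.
#' @export
plant_hotspots <- function(genome, n, motifs,
                           allele_mix = NULL, min_spacing = 10000,
                           multi_motif_fraction = 0, edge_margin = 5000,
                           strength_sdlog = 1, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(names(motifs))) abort("motifs must be named by allele")
  if (any(nchar(motifs) >= min_spacing)) {
    abort("motif length must be smaller than min_spacing")
  }
  if (is.null(allele_mix)) {
    allele_mix <- setNames(rep(1 / length(motifs), length(motifs)),
                           names(motifs))
  }
  if (!setequal(names(allele_mix), names(motifs))) {
    abort("allele_mix names must match motifs")
  }
  local_seed_if(seed)

  # per-chrom capacity with the exact spacing construction below:
  # n_c centers fit iff span - (n_c - 1) * min_spacing >= 0
  spans <- pmax(0, genome$lengths - 2 * edge_margin)
  caps <- pmax(0, floor(spans / min_spacing) + as.integer(spans > 0))
  if (sum(caps) < n) {
    abort(sprintf("cannot place %d hotspots at spacing %d in this genome",
                  n, min_spacing))
  }
  # allocate counts across chromosomes ~ length, capped, then place each
  # chromosome's centers as sorted uniforms stretched by the min spacing
  # (guarantees pairwise distances >= min_spacing without rejection)
  slots <- rep(names(genome$lengths), caps)
  pool <- sample(slots, n)
  alloc <- table(factor(pool, levels = names(genome$lengths)))
  centers <- imap(alloc[alloc > 0], function(n_c, chrom) {
    span <- genome$lengths[[chrom]] - 2 * edge_margin
    slack <- span - (n_c - 1) * min_spacing
    u <- sort(runif(n_c, 0, slack))
    tibble(chrom = chrom,
           center = floor(edge_margin + u +
                            (seq_len(n_c) - 1) * min_spacing))
  }) |> list_rbind()

  allele <- sample(names(allele_mix), n, replace = TRUE, prob = allele_mix)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  strength <- stats::rlnorm(n, meanlog = 0, sdlog = strength_sdlog)
  n_multi <- round(n * multi_motif_fraction)
  multi <- rep(FALSE, n)
  if (n_multi > 0) multi[sample.int(n, n_multi)] <- TRUE

  truth <- centers |>
    mutate(allele = allele, strand = strand, strength = strength,
           n_motifs = ifelse(multi, 2L, 1L)) |>
    arrange(.data$chrom, .data$center)

  seqs <- genome$sequences
  for (i in seq_len(nrow(truth))) {
    m <- motifs[[truth$allele[i]]]
    if (truth$strand[i] == "-") m <- revcomp(m)
    start0 <- truth$center[i] - floor(nchar(m) / 2)
    seqs[[truth$chrom[i]]] <-
      splice_sequence(seqs[[truth$chrom[i]]], start0, m)
    if (truth$n_motifs[i] == 2L) {
      seqs[[truth$chrom[i]]] <-
        splice_sequence(seqs[[truth$chrom[i]]], start0 + 300, m)
    }
  }
  genome$sequences <- seqs
  list(genome = genome, truth = truth)
}

#' Hotspot intervals from a truth table
#'
#' @param truth Hotspot truth tibble (see [plant_hotspots()]).
#' @param halfwidth Interval half-width around each center (bp, default
#'   500).
#' @return Interval tibble.
#' @export
hotspot_intervals <- function(truth, halfwidth = 500) {
  tibble(chrom = truth$chrom,
         start = truth$center - halfwidth,
         end = truth$center + halfwidth) |>
    arrange(.data$chrom, .data$start)
}
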