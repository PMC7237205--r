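#' Read / write an aligned protein FASTA
#'
#' @param path File path.
#' @return Named character vector of equal-length aligned sequences
#'   (residues and `-`).
#' @export
read_msa <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  msa <- setNames(as.character(x), names(x))
  check_msa(msa)
  msa
}

#' @rdname read_msa
#' @param msa Named character vector of aligned sequences.
#' @export
write_msa <- function(msa, path) {
  check_msa(msa)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), path)
  invisible(path)
}

check_msa <- function(msa) {
  if (is.null(names(msa)) || any(!nzchar(names(msa)))) {
    abort("alignment sequences must be named")
  }
  if (length(unique(nchar(msa))) != 1L) {
    abort("aligned sequences must have equal length")
  }
  invisible(msa)
}

msa_matrix <- function(msa) {
  check_msa(msa)
  do.call(rbind, strsplit(toupper(msa), ""))
}

#' Pair dual-domain hits into candidate loci
#'
#' The dual-domain ortholog screen: a subject sequence is a candidate
#' locus iff it carries at least one hit for each of the two query domains
#' (zf-CW and PWWP) and the distance between the two aligned regions does
#' not exceed `max_distance` (inclusive). Distance is the gap between the
#' nearest ends of the two regions, 0 when they overlap. When several
#' pairings are possible on one subject, the best-scoring pair (largest
#' score sum) is kept.
#'
#' @param hits Tibble with columns `species`, `subject`, `domain` (values
#'   `"zf-CW"` / `"PWWP"`), `start`, `end`, `score`.
#' @param max_distance Maximum inter-domain distance in bp (default
#'   50000, inclusive).
#' @param domains Length-2 character, the two required domain labels.
#' @return Tibble of candidate loci: `species`, `subject`, per-domain
#'   coordinates, `distance`, `score`.
#' @export
pair_domain_hits <- function(hits, max_distance = 50000,
                             domains = c("zf-CW", "PWWP")) {
  req <- c("species", "subject", "domain", "start", "end", "score")
  if (!all(req %in% names(hits))) {
    abort("hits must have columns species, subject, domain, start, end, score")
  }
  if (any(hits$start >= hits$end)) abort("domain hit with start >= end")
  hits |>
    filter(.data$domain %in% domains) |>
    group_by(.data$species, .data$subject) |>
    group_modify(function(d, key) {
      a <- d[d$domain == domains[1], ]
      b <- d[d$domain == domains[2], ]
      if (nrow(a) == 0L || nrow(b) == 0L) return(tibble())
      pairs <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      pairs <- pairs |>
        mutate(
          distance = pmax(0, pmax(a$start[.data$i], b$start[.data$j]) -
                            pmin(a$end[.data$i], b$end[.data$j])),
          score = a$score[.data$i] + b$score[.data$j]
        ) |>
        filter(.data$distance <= max_distance)
      if (nrow(pairs) == 0L) return(tibble())
      bestp <- pairs |> arrange(desc(.data$score), .data$distance) |> slice(1)
      tibble(
        zfcw_start = a$start[bestp$i], zfcw_end = a$end[bestp$i],
        pwwp_start = b$start[bestp$j], pwwp_end = b$end[bestp$j],
        distance = bestp$distance, score = bestp$score
      )
    }) |>
    ungroup()
}

# p-distance with pairwise gap deletion between two rows of a char matrix
p_distance_matrix <- function(mat) {
  gap <- mat == "-" | mat == "." | mat == "X"
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      d[i, j] <- d[j, i] <- if (ns == 0L) 1 else {
        sum(mat[i, shared] != mat[j, shared]) / ns
      }
    }
  }
  d
}

# Tip ids of the clade below each internal node of a rooted ape::phylo
node_tipsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; child <- edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

assign_one_tree <- function(tree, candidates, family1_refs, family2_refs,
                            outgroup) {
  tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  n_tip <- length(tree$tip.label)
  sets <- node_tipsets(tree)
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(candidates, function(cand) {
    node <- match(cand, tree$tip.label)
    repeat {
      node <- parent_of[node]
      if (node == 0L) return("unresolved")
      tips <- sets[[node]]
      has1 <- any(family1_refs %in% tips)
      has2 <- any(family2_refs %in% tips)
      if (has1 && has2) return("unresolved")
      if (has1) return("family1")
      if (has2) return("family2")
    }
  }, character(1))
}

#' Assign candidate sequences to one of two paralog families
#'
#' Builds a neighbor-joining tree on p-distances (pairwise gap deletion)
#' from the alignment of candidates plus known references of the two
#' families, roots it at the outgroup, and assigns each candidate to the
#' family whose references share its smallest enclosing clade that
#' excludes the other family's references (walking from the candidate tip
#' toward the root; a clade containing both families' references yields
#' `"unresolved"`). Support is the fraction of column-bootstrap NJ trees
#' agreeing with the point assignment.
#'
#' @param msa Named character vector: aligned candidates + references +
#'   outgroup.
#' @param family1_refs,family2_refs Character vectors of reference ids.
#' @param outgroup Outgroup sequence id.
#' @param n_bootstrap Number of column bootstraps (default 100).
#' @param seed Optional seed for the bootstrap resampling.
#' @return Tibble `id`, `family` (`"family1"`, `"family2"`,
#'   `"unresolved"`), `support`; attribute `tree` holds the point-estimate
#'   `phylo`.
#' @export
assign_paralog <- function(msa, family1_refs, family2_refs, outgroup,
                           n_bootstrap = 100, seed = NULL) {
  check_msa(msa)
  ids <- names(msa)
  need <- c(family1_refs, family2_refs, outgroup)
  if (!all(need %in% ids)) abort("references/outgroup missing from alignment")
  if (!length(family1_refs) || !length(family2_refs)) {
    abort("need at least one reference per family")
  }
  candidates <- setdiff(ids, need)
  mat <- msa_matrix(msa)
  rownames(mat) <- ids
  tree <- ape::nj(as.dist(p_distance_matrix(mat)))
  point <- assign_one_tree(tree, candidates, family1_refs, family2_refs,
                           outgroup)
  support <- rep(NA_real_, length(candidates))
  if (n_bootstrap > 0 && length(candidates)) {
    local_seed_if(seed)
    agree <- matrix(0L, length(candidates), n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      bt <- ape::nj(as.dist(p_distance_matrix(mat[, cols, drop = FALSE])))
      ab <- assign_one_tree(bt, candidates, family1_refs, family2_refs,
                            outgroup)
      agree[, b] <- as.integer(ab == point)
    }
    support <- rowMeans(agree)
  }
  out <- tibble(id = candidates, family = unname(point), support = support)
  attr(out, "tree") <- tree
  out
}

#' Per-column conservation and Shannon entropy along a reference
#'
#' Alignment columns where the reference has a gap are removed, so the
#' profile has exactly one row per reference residue. Within each retained
#' column, gap characters are excluded and residue frequencies
#' renormalized; the conservation score is the maximum residue frequency
#' and the entropy is `H = -sum(p * log2(p))` in bits. Columns where every
#' other sequence is gapped are flagged missing.
#'
#' @param msa Named character vector of aligned sequences.
#' @param reference_id Id of the reference sequence.
#' @return Tibble: `ref_pos` (1-based ungapped reference position),
#'   `column` (alignment column), `ref_residue`, `score`, `entropy`,
#'   `n_residues`.
#' @export
conservation_profile <- function(msa, reference_id) {
  mat <- msa_matrix(msa)
  rownames(mat) <- names(msa)
  if (!reference_id %in% names(msa)) abort("reference not in alignment")
  ref <- mat[reference_id, ]
  keep <- which(ref != "-")
  map(seq_along(keep), function(k) {
    col <- mat[, keep[k]]
    res <- col[col != "-" & col != "."]
    if (!length(res)) {
      return(tibble(ref_pos = k, column = keep[k], ref_residue = ref[keep[k]],
                    score = NA_real_, entropy = NA_real_, n_residues = 0L))
    }
    p <- table(res) / length(res)
    tibble(ref_pos = k, column = keep[k], ref_residue = ref[keep[k]],
           score = max(as.numeric(p)),
           entropy = -sum(as.numeric(p) * log2(as.numeric(p))),
           n_residues = length(res))
  }) |> list_rbind()
}

#' Count conserved catalytic residues per sequence
#'
#' Maps 1-based ungapped reference positions (by default the three
#' catalytic tyrosines of the PRDM9 SET domain) to alignment columns via
#' the cumulative non-gap count, then counts, for every sequence, the
#' mapped columns carrying the queried residue. The reference must itself
#' carry the queried residue at each position; a mismatch signals a
#' position/isoform numbering problem and raises an error.
#'
#' @param msa Named character vector of aligned sequences.
#' @param reference_id Reference sequence id.
#' @param positions 1-based ungapped reference positions
#'   (default `c(276, 341, 357)`).
#' @param residue Single-letter residue required (default `"Y"`).
#' @return Tibble `id`, `n_conserved` (0..length(positions)); attribute
#'   `columns` gives the mapped alignment columns.
#' @export
catalytic_conservation <- function(msa, reference_id,
                                   positions = c(276, 341, 357),
                                   residue = "Y") {
  mat <- msa_matrix(msa)
  rownames(mat) <- names(msa)
  if (!reference_id %in% names(msa)) abort("reference not in alignment")
  ref <- mat[reference_id, ]
  ungapped <- cumsum(ref != "-")
  if (any(positions > max(ungapped))) {
    abort("position beyond reference ungapped length")
  }
  cols <- vapply(positions, function(p) which(ungapped == p & ref != "-")[1],
                 integer(1))
  bad <- ref[cols] != residue
  if (any(bad)) {
    abort(sprintf(
      "reference residue at position %d is '%s', not '%s' (isoform mismatch?)",
      positions[which(bad)[1]], ref[cols[which(bad)[1]]], residue))
  }
  out <- tibble(
    id = names(msa),
    n_conserved = unname(apply(mat[, cols, drop = FALSE] == residue, 1,
                               function(v) sum(v)))
  )
  attr(out, "columns") <- cols
  out
}

#' Percent identity between two aligned sequences
#'
#' Matches divided by columns where both sequences are non-gap.
#'
#' @param msa Named character vector of aligned sequences.
#' @param id_a,id_b Sequence ids.
#' @return Numeric in \[0, 1\].
#' @export
percent_identity <- function(msa, id_a, id_b) {
  mat <- msa_matrix(msa)
  rownames(mat) <- names(msa)
  if (!all(c(id_a, id_b) %in% names(msa))) abort("sequence id not found")
  a <- mat[id_a, ]; b <- mat[id_b, ]
  shared <- a != "-" & b != "-"
  if (!any(shared)) abort("no shared non-gap columns")
  sum(a[shared] == b[shared]) / sum(shared)
}
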