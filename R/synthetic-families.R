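AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

mutate_residues <- function(res, idx) {
  if (!length(idx)) return(res)
  res[idx] <- vapply(res[idx], function(a) {
    sample(setdiff(AA_ALPHABET, a), 1)
  }, character(1))
  res
}

#' Simulate a two-clade protein family alignment with domain hits
#'
#' Builds a gapless alignment of two paralog clades plus an outgroup from
#' a common root sequence: each clade gets its own consensus (the root
#' mutated at a clade-specific set of variable positions), and each
#' member sequence mutates the clade consensus per column with probability
#' `1 - conservation`, so within-clade identity exceeds between-clade
#' identity. Columns inside `domain_blocks` are held at
#' `domain_conservation`; columns at conservation 1 are invariant across
#' the whole family. Catalytic columns are set to the catalytic residue in
#' the reference and toggled per sequence according to
#' `catalytic_states`.
#'
#' Alongside the alignment a domain-hit table is emitted with per-species
#' genomic-scale coordinates for the two domains, with configurable
#' inter-domain distances so the 50 kb pairing rule can be exercised.
#'
#' @param n1,n2 Number of sequences in family 1 / family 2 (the first
#'   family-1 sequence is the flagged reference).
#' @param length Protein length (columns; default 400).
#' @param domain_blocks Named list of 1-based column ranges, e.g.
#'   `list("zf-CW" = c(241, 295), PWWP = c(308, 374))`.
#' @param background_conservation,domain_conservation Per-column identity
#'   probabilities in \[0, 1\] outside / inside domain blocks (defaults
#'   0.7 and 0.98).
#' @param invariant_columns Integer columns forced to conservation 1.
#' @param clade_divergence Fraction of non-domain columns whose consensus
#'   differs between the two clades (default 0.3).
#' @param catalytic_positions Columns carrying the catalytic residue
#'   (default `c(276, 341, 357)`).
#' @param catalytic_residue Single letter (default `"Y"`).
#' @param catalytic_states Optional named list: per sequence id, a logical
#'   vector over `catalytic_positions` saying which are retained (missing
#'   ids retain all; lost positions become `"F"`).
#' @param inter_domain_distances Numeric vector (recycled over species) of
#'   genomic distances between the two domain hits in the emitted hit
#'   table; default `c(100, 2000, 60000)` so some loci violate the 50 kb
#'   rule.
#' @param outgroup Include an outgroup sequence (default TRUE).
#' @param seed Optional seed.
#' @return List with `msa` (named character vector), `hits` (DomainHit
#'   tibble), `truth` (tibble: `id`, `family`, `is_reference`,
#'   `n_catalytic`).
#' @export
simulate_protein_families <- function(
    n1 = 8, n2 = 8, length = 400,
    domain_blocks = list("zf-CW" = c(241, 295), "PWWP" = c(308, 374)),
    background_conservation = 0.7, domain_conservation = 0.98,
    invariant_columns = integer(0),
    clade_divergence = 0.3,
    catalytic_positions = c(276, 341, 357), catalytic_residue = "Y",
    catalytic_states = NULL,
    inter_domain_distances = c(100, 2000, 60000),
    outgroup = TRUE, seed = NULL) {
  if (background_conservation < 0 || background_conservation > 1 ||
      domain_conservation < 0 || domain_conservation > 1) {
    abort("conservation levels must be in [0, 1]")
  }
  local_seed_if(seed)

  conservation <- rep(background_conservation, length)
  for (blk in domain_blocks) {
    conservation[blk[1]:blk[2]] <- domain_conservation
  }
  conservation[invariant_columns] <- 1
  conservation[catalytic_positions] <- 1   # catalytic state set explicitly

  root <- sample(AA_ALPHABET, length, replace = TRUE)
  root[catalytic_positions] <- catalytic_residue

  variable <- setdiff(which(conservation < 1), catalytic_positions)
  n_div <- round(clade_divergence * base::length(variable))
  div_cols <- sample(variable, n_div)
  cons1 <- root
  cons2 <- mutate_residues(root, div_cols)

  ids <- c(paste0("F1_", c("ref", sprintf("sp%02d", seq_len(max(0, n1 - 1))))),
           paste0("F2_", sprintf("sp%02d", seq_len(n2))))
  families <- c(rep("family1", n1), rep("family2", n2))
  msa <- setNames(vector("character", n1 + n2), ids)
  for (i in seq_along(ids)) {
    cons <- if (families[i] == "family1") cons1 else cons2
    res <- cons
    if (!(ids[i] == "F1_ref")) {
      flip <- which(runif(length) > conservation)
      flip <- setdiff(flip, catalytic_positions)
      res <- mutate_residues(res, flip)
    }
    keep <- rep(TRUE, base::length(catalytic_positions))
    if (!is.null(catalytic_states) && ids[i] %in% names(catalytic_states)) {
      keep <- rep_len(as.logical(catalytic_states[[ids[i]]]),
                      base::length(catalytic_positions))
    }
    res[catalytic_positions[!keep]] <- "F"
    res[catalytic_positions[keep]] <- catalytic_residue
    msa[ids[i]] <- paste(res, collapse = "")
  }
  if (outgroup) {
    og <- mutate_residues(root, sample.int(length, round(0.5 * length)))
    og[catalytic_positions] <- catalytic_residue
    msa <- c(msa, outgroup = paste(og, collapse = ""))
  }

  truth <- tibble(
    id = ids, family = families,
    is_reference = ids == "F1_ref",
    n_catalytic = vapply(ids, function(id) {
      res <- strsplit(msa[[id]], "")[[1]]
      sum(res[catalytic_positions] == catalytic_residue)
    }, integer(1), USE.NAMES = FALSE)
  )

  dists <- rep_len(inter_domain_distances, base::length(ids))
  hits <- map(seq_along(ids), function(i) {
    zf_start <- 1000
    zf_end <- zf_start + 3 * diff(domain_blocks[[1]]) # nt scale
    pw_start <- zf_end + dists[i]
    tibble(species = ids[i], subject = paste0("acc_", ids[i]),
           domain = c(names(domain_blocks)[1], names(domain_blocks)[2]),
           start = c(zf_start, pw_start),
           end = c(zf_end, pw_start + 3 * diff(domain_blocks[[2]])),
           score = c(100, 100))
  }) |> list_rbind()

  list(msa = msa, hits = hits, truth = truth)
}
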