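#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap list_rbind
#' @importFrom stats ppois qpois pnorm qnorm rnorm runif rpois rbinom rexp
#'   setNames median cor hclust dist as.dist wilcox.test pt complete.cases
#' @importFrom utils head tail combn
NULL

# Local seeding: all generators funnel randomness through this so that a
# given seed yields byte-identical output without disturbing the caller's RNG.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# Genome declarations are named numeric vectors (chrom -> length in bp).
check_genome <- function(genome) {
  if (is.data.frame(genome)) {
    genome <- setNames(as.numeric(genome[[2]]), as.character(genome[[1]]))
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("genome declaration must be a named vector (chrom -> length)")
  }
  if (any(genome <= 0)) abort("chromosome lengths must be positive")
  genome
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a tab-delimited file with columns chrom and length.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  check_genome(setNames(x$length, x$chrom))
}

# Convert an interval tibble (chrom, start, end; 0-based half-open) to GRanges.
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

check_intervals <- function(x, genome = NULL, what = "intervals") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(paste0(what, ": require 0 <= start < end (0-based half-open)"))
  }
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    bad <- !(x$chrom %in% names(genome))
    if (any(bad)) abort(paste0(what, ": unknown chrom ", unique(x$chrom[bad])[1]))
    if (any(x$end > genome[x$chrom])) {
      abort(paste0(what, ": interval end exceeds chromosome length"))
    }
  }
  invisible(x)
}

# Spearman rho with average ranks, plus two-sided p.
# For n <= perm_cutoff the p-value is an exact permutation tail probability
# (fraction of permutations with |rho| >= observed); otherwise the
# t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df.
spearman_cor <- function(x, y, p_method = c("auto", "t", "permutation"),
                         perm_cutoff = 10L) {
  p_method <- match.arg(p_method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("Spearman rho undefined for a constant variable")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_perm <- p_method == "permutation" ||
    (p_method == "auto" && n <= perm_cutoff)
  if (use_perm) {
    if (n > 10L) abort("exact permutation p only supported for n <= 10")
    perms <- permutations_all(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  k <- 1L
  for (i in seq_len(n)) {
    block <- cbind(rep(i, nrow(sub)), sub + (sub >= i))
    out[k:(k + nrow(sub) - 1L), ] <- block
    k <- k + nrow(sub)
  }
  out
}
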