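#' Simulate a UMI count matrix with planted rank correlations
#'
#' Gaussian-copula counts: a latent standard normal per cell drives the
#' target gene, and each planted gene's latent value correlates with it at
#' the Pearson level `2 * sin(pi * rho / 6)` so the latent Spearman
#' correlation equals the planted `rho`. Latents are mapped to counts via
#' the Poisson quantile function with per-gene mean expression and
#' per-cell depth factors (Poisson thinning), which preserves ranks up to
#' discretization ties.
#'
#' @param n_genes Total number of genes (unplanted genes get rho 0).
#' @param n_cells Number of cells.
#' @param target_gene Name of the target gene row (default `"Prdm9"`).
#' @param planted_rho Named numeric vector of Spearman correlations in
#'   `(-0.95, 0.95)` for planted genes (names become gene ids).
#' @param depth_range Per-cell depth factor range, uniform (default
#'   `c(0.5, 1.5)`).
#' @param mean_expression Mean counts per gene at unit depth; recycled
#'   (default 5 for planted genes and the target, lognormal around 2 for
#'   background genes).
#' @param seed Optional seed.
#' @return Integer matrix genes x cells with attribute `planted_rho`
#'   (named, full length) and `depth_factors`.
#' @export
simulate_sc_counts <- function(n_genes, n_cells, target_gene = "Prdm9",
                               planted_rho = numeric(0),
                               depth_range = c(0.5, 1.5),
                               mean_expression = 5, seed = NULL) {
  if (any(abs(planted_rho) > 0.95)) {
    abort("|rho| > 0.95 is distorted by the copula; choose a smaller value")
  }
  if (length(planted_rho) &&
      (is.null(names(planted_rho)) || any(!nzchar(names(planted_rho))))) {
    abort("planted_rho must be named by gene")
  }
  n_bg <- n_genes - length(planted_rho) - 1L
  if (n_bg < 0) abort("n_genes too small for the planted genes + target")
  local_seed_if(seed)

  genes <- c(target_gene, names(planted_rho),
             if (n_bg > 0) sprintf("gene%04d", seq_len(n_bg)))
  rho_full <- setNames(c(1, as.numeric(planted_rho), rep(0, n_bg)), genes)

  depth <- runif(n_cells, depth_range[1], depth_range[2])
  mu <- rep_len(mean_expression, length(planted_rho) + 1L)
  mu_bg <- if (n_bg > 0) stats::rlnorm(n_bg, log(2), 0.8) else numeric(0)
  mu_all <- setNames(c(mu, mu_bg), genes)

  z0 <- rnorm(n_cells)
  m <- matrix(0L, nrow = length(genes), ncol = n_cells,
              dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  for (g in genes) {
    rho_s <- rho_full[[g]]
    r <- 2 * sin(pi * rho_s / 6)          # Spearman -> Pearson on latents
    z <- if (g == target_gene) z0 else {
      r * z0 + sqrt(1 - r^2) * rnorm(n_cells)
    }
    lam <- mu_all[[g]] * depth
    m[g, ] <- qpois(pnorm(z), lam)
  }
  attr(m, "planted_rho") <- rho_full
  attr(m, "depth_factors") <- depth
  m
}
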