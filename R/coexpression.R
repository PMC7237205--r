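as_count_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    gene_col <- names(x)[1]
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[gene_col]])
    return(m)
  }
  abort("counts must be a matrix (genes x cells) or tibble with a gene column")
}

#' Read / write a dense gene-by-cell count matrix as TSV
#'
#' Genes are rows; the first column holds gene ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_umi_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  as_count_matrix(x)
}

#' @rdname read_umi_matrix
#' @param m Matrix with gene rownames.
#' @export
write_umi_matrix <- function(m, path) {
  out <- as_tibble(m, rownames = "gene")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Depth-normalize UMI counts
#'
#' Per-cell size factor = cell total / median(cell totals); values become
#' `log2(count / size_factor + 1)`. All-zero cells are dropped with a
#' warning. A simple, documented scheme: downstream statistics are
#' rank-based, so sensitivity to the normalization flavour is low.
#'
#' @param counts Genes x cells matrix (or tibble with gene id column).
#' @return Normalized numeric matrix; attribute `size_factors` records the
#'   per-cell factors.
#' @export
normalize_counts <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  totals <- colSums(m)
  if (all(totals == 0)) abort("all cells have zero counts")
  if (any(totals == 0)) {
    warn(sprintf("dropped %d all-zero cells", sum(totals == 0)))
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  sf <- totals / median(totals)
  out <- log2(sweep(m, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Rank genes by Spearman co-expression with a target gene
#'
#' Computes Spearman's rho between every gene and the target gene across
#' cells (average ranks for ties) and returns a table sorted by rho
#' descending with two-sided p-values — the screen that surfaces reader
#' candidates co-expressed with Prdm9 in meiotic single cells. Genes
#' expressed in fewer than `min_cells_frac` of cells, and constant genes,
#' are excluded (recorded in attribute `excluded`).
#'
#' @param mat Normalized (or raw) genes x cells matrix.
#' @param target_gene Row name of the target gene.
#' @param min_cells_frac Minimum fraction of cells with nonzero counts for
#'   a gene to enter the ranking (default 0.05).
#' @param p_method `"auto"` (exact permutation for <= 10 cells, otherwise
#'   t approximation), `"t"`, or `"permutation"`.
#' @return Tibble `gene`, `rho`, `p`, `rank` (1 = most correlated;
#'   the target itself is included with rho 1).
#' @export
spearman_coexpression <- function(mat, target_gene, min_cells_frac = 0.05,
                                  p_method = c("auto", "t", "permutation")) {
  p_method <- match.arg(p_method)
  m <- as_count_matrix(mat)
  if (!target_gene %in% rownames(m)) abort("target gene not in matrix")
  tgt <- m[target_gene, ]
  if (length(unique(tgt)) == 1L) abort("target gene is constant")
  expressed <- rowMeans(m > 0) >= min_cells_frac
  constant <- apply(m, 1, function(v) length(unique(v)) == 1L)
  keep <- expressed & !constant
  keep[target_gene] <- TRUE
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  res <- map(rownames(m), function(g) {
    r <- spearman_cor(m[g, ], tgt, p_method = p_method)
    tibble(gene = g, rho = r$rho, p = r$p)
  }) |> list_rbind()
  res <- res |>
    arrange(desc(.data$rho)) |>
    mutate(rank = row_number())
  attr(res, "excluded") <- excluded
  res
}

#' Hierarchical leaf order of cells over the top co-expressed genes
#'
#' Orders cells (columns) by agglomerative clustering of the submatrix of
#' the top-k genes, for heatmap display: euclidean distance, complete
#' linkage by default. Ties are resolved deterministically by column index
#' (the order `stats::hclust` receives).
#'
#' @param mat Normalized genes x cells matrix.
#' @param genes Character vector of gene ids (rows) to use; at least 2.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return Integer vector: column (cell) leaf order.
#' @export
hierarchical_order <- function(mat, genes, metric = "euclidean",
                               linkage = "complete") {
  m <- as_count_matrix(mat)
  if (length(genes) < 2L) abort("need at least 2 genes")
  if (!all(genes %in% rownames(m))) abort("genes missing from matrix")
  sub <- m[genes, , drop = FALSE]
  if (any(!is.finite(sub))) abort("matrix contains non-finite values")
  hc <- hclust(dist(t(sub), method = metric), method = linkage)
  hc$order
}

#' Heatmap of the top co-expressed genes
#'
#' @param mat Normalized genes x cells matrix.
#' @param coexpr Output of [spearman_coexpression()].
#' @param top Number of top-ranked genes to show (default 25).
#' @return A ggplot tile heatmap, genes ordered by rho, cells by
#'   hierarchical clustering.
#' @export
plot_coexpression_heatmap <- function(mat, coexpr, top = 25) {
  m <- as_count_matrix(mat)
  genes <- head(coexpr$gene, top)
  ord <- hierarchical_order(m, genes)
  df <- as_tibble(m[genes, ord, drop = FALSE], rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "value") |>
    mutate(gene = factor(.data$gene, levels = rev(genes)),
           cell = factor(.data$cell, levels = colnames(m)[ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
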