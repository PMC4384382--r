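#' Shifted-log transform of size-factor-normalized counts
#'
#' Computes `log2(K/s + 1)` for every count, a variance-moderating
#' log-scale transform: the +1 shift keeps low-count genes from dominating
#' distance computations, in the spirit of regularized-log transforms, while
#' remaining deterministic and model-free. Zero counts map to exactly 0 and
#' the transform is monotone in the counts within a sample.
#'
#' @param counts Wide counts tibble.
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @return A wide tibble of transformed values, same shape as `counts`.
#' @export
rlog_surrogate <- function(counts, sf = NULL) {
  m <- check_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  if (anyNA(s) || any(s <= 0)) {
    stop_atlas("valid size factors required for every sample", "validation")
  }
  gene_matrix_to_tibble(log2(sweep(m, 2, s, `/`) + 1))
}

#' Select the highest-variance genes
#'
#' Ranks genes by their across-sample variance (denominator n - 1) of the
#' transformed expression values and returns the top fraction. Ties are
#' broken by gene identifier order so the selection is deterministic.
#'
#' @param tm Transformed matrix (wide tibble, e.g. from
#'   [rlog_surrogate()]).
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return A tibble (`gene_id`, `variance`) with `ceiling(fraction * n)`
#'   rows, in decreasing variance order.
#' @export
top_variance_genes <- function(tm, fraction = 0.5) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_atlas("fraction must lie in (0, 1]", "validation")
  }
  m <- as_gene_matrix(tm)
  if (ncol(m) < 2) stop_atlas("need at least 2 samples", "validation")
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  keep <- ord[seq_len(ceiling(fraction * nrow(m)))]
  tibble::tibble(gene_id = rownames(m)[keep], variance = unname(v[keep]))
}

#' Hierarchical clustering of samples or genes
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' between the chosen items' expression profiles. The result is the
#' standard `hclust` object (merge order, heights, labels), so all base
#' dendrogram tooling applies; [write_dendrogram()] exports Newick.
#'
#' @param tm Transformed matrix (wide tibble).
#' @param axis `"samples"` (cluster columns) or `"genes"` (cluster rows).
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(tm, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  m <- as_gene_matrix(tm)
  x <- if (axis == "samples") t(m) else m
  if (nrow(x) < 2) {
    stop_atlas("need at least 2 items to cluster", "validation")
  }
  hclust(dist(x, method = "euclidean"), method = "complete")
}

#' Write a dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis of samples
#'
#' Gene-centered PCA of the samples (each gene's mean across samples is
#' subtracted; no scaling). Components are ordered by explained variance;
#' the sign of each component is fixed so that its largest-magnitude gene
#' loading is positive, making results reproducible across platforms.
#'
#' @param tm Transformed matrix (wide tibble).
#' @param samples Optional sample sheet; if given, subtype labels are
#'   attached to the scores for plotting.
#' @return An object of class `"atlas_pca"`: list with `scores` (tibble
#'   `sample_id`, `PC1`..., optional `subtype`), `explained` (variance
#'   fractions, non-increasing), `rotation` (gene loadings) and `center`.
#' @export
pca_samples <- function(tm, samples = NULL) {
  m <- as_gene_matrix(tm)
  if (ncol(m) < 2) stop_atlas("need at least 2 samples", "validation")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- tibble::add_column(scores, sample_id = rownames(pc$x), .before = 1)
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores,
                               samples[, c("sample_id", "subtype")],
                               by = "sample_id")
  }
  structure(list(scores = scores, explained = explained,
                 rotation = pc$rotation, center = pc$center),
            class = "atlas_pca")
}

#' @export
print.atlas_pca <- function(x, ...) {
  k <- min(4, length(x$explained))
  cat(sprintf("PCA of %d samples; variance explained: %s\n",
              nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$explained[seq_len(k)]), collapse = ", ")))
  invisible(x)
}
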