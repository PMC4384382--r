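#' Median-of-ratios size factors
#'
#' Computes one positive scaling constant per sample so that samples
#' sequenced to different depths become comparable. The reference for each
#' gene is the geometric mean of its counts across samples; a sample's size
#' factor is the median, over genes, of the ratio of its count to that
#' reference. Genes with a zero count in any sample are excluded from the
#' reference (their geometric mean would be zero), which makes the estimate
#' robust to strong differential expression of a few highly expressed
#' genes.
#'
#' @param counts Wide counts tibble (`gene_id` + one integer column per
#'   sample).
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                          s1 = c(10L, 100L, 1000L),
#'                          s2 = c(20L, 200L, 2000L))
#' size_factors(counts) # 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  m <- check_counts(counts)
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop_atlas("no gene has strictly positive counts in every sample",
               "normalization")
  }
  mm <- m[usable, , drop = FALSE]
  log_geo <- rowMeans(log(mm))
  ratios <- mm / exp(log_geo)
  tibble::tibble(
    sample_id = colnames(m),
    size_factor = unname(apply(ratios, 2, median))
  )
}

#' Size-factor-adjusted, length-normalized expression
#'
#' Divides each count by its sample's size factor and by the gene length in
#' kilobases, giving a measure equivalent to RPKM and comparable across
#' both samples and genes.
#'
#' @param counts Wide counts tibble.
#' @param genes Gene annotation tibble with `gene_id` and `length_bp`.
#' @param sf Size factors from [size_factors()], or `NULL` to compute them.
#' @return A wide tibble of the same shape as `counts` with non-negative
#'   real values; a value is zero exactly where the count is zero.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 100L, s2 = 100L)
#' genes <- tibble::tibble(gene_id = "g1", length_bp = 1000L)
#' normalize_counts(counts, genes)
normalize_counts <- function(counts, genes, sf = NULL) {
  m <- check_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  if (!all(colnames(m) %in% sf$sample_id)) {
    stop_atlas("size factors missing for some samples", "validation")
  }
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop_atlas("size factors must be positive", "validation")
  }
  idx <- match(rownames(m), genes$gene_id)
  if (anyNA(idx)) {
    missing <- rownames(m)[is.na(idx)]
    stop_atlas(sprintf("no annotated length for gene(s): %s",
                       paste(head(missing, 5), collapse = ", ")),
               "annotation")
  }
  len_kb <- genes$length_bp[idx] / 1000
  if (any(!is.finite(len_kb)) || any(len_kb <= 0)) {
    stop_atlas("gene lengths must be positive", "annotation")
  }
  norm <- sweep(m, 2, s, `/`) / len_kb
  gene_matrix_to_tibble(norm)
}
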