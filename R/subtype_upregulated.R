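#' Call subtype-upregulated (SU) genes
#'
#' A gene is subtype-upregulated for subtype `t` when it is significantly
#' upregulated (`padj <= padj_max` and `log2fc > 0` towards `t`) in
#' *every* pairwise comparison of `t` against the other subtypes, and its
#' expression class in `t` is INT or HE. Untestable comparisons (e.g. the
#' gene is not expressed in either subtype of a pair) count as failures:
#' the "every comparison" rule is conjunctive. SU sets are pairwise
#' disjoint across subtypes by construction.
#'
#' @param de Pairwise DE table from [pairwise_de()].
#' @param classes Class assignments from [assign_classes()].
#' @param subtypes Subtypes to call SU genes for (default: all subtypes in
#'   `classes`).
#' @param padj_max Significance threshold (default 0.01).
#' @return A tibble (`subtype`, `gene_id`, `min_log2fc`, `max_padj`), where
#'   `min_log2fc` is the weakest upregulation and `max_padj` the weakest
#'   significance over the subtype's comparisons.
#' @export
call_su_genes <- function(de, classes, subtypes = NULL, padj_max = 0.01) {
  all_subtypes <- unique(classes$subtype)
  if (is.null(subtypes)) subtypes <- all_subtypes
  purrr::map(subtypes, function(st) {
    others <- setdiff(all_subtypes, st)
    # Orient every comparison so that positive log2fc means "up in st".
    rows <- de[de$subtype_a == st | de$subtype_b == st, ]
    rows$other <- ifelse(rows$subtype_a == st, rows$subtype_b, rows$subtype_a)
    rows$lfc_st <- ifelse(rows$subtype_b == st, rows$log2fc, -rows$log2fc)
    if (!all(others %in% rows$other)) {
      stop_atlas(sprintf("DE table is missing comparisons for subtype '%s'",
                         st), "incomplete")
    }
    ev <- rows |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        n_pass = sum(!is.na(.data$padj) & .data$padj <= padj_max &
                       .data$lfc_st > 0),
        n_cmp = dplyr::n(),
        min_log2fc = min(.data$lfc_st),
        max_padj = max(.data$padj),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n_pass == length(others), .data$n_cmp == length(others))
    cls <- classes$gene_id[classes$subtype == st &
                             classes$class %in% c("INT", "HE")]
    ev <- ev[ev$gene_id %in% cls, ]
    tibble::tibble(subtype = st, gene_id = ev$gene_id,
                   min_log2fc = ev$min_log2fc, max_padj = ev$max_padj)
  }) |> dplyr::bind_rows()
}

#' Break down SU gene sets by functional category
#'
#' Intersects each subtype's SU gene set with the annotation's functional
#' categories (transcription factors, cytokines, receptors, lncRNAs,
#' other) and reports per-category member lists and counts. Category
#' counts partition each SU set.
#'
#' @param su SU gene table from [call_su_genes()].
#' @param genes Gene annotation tibble with `gene_id` and `category`.
#' @return A tibble (`subtype`, `category`, `n`, `gene_ids` list-column).
#' @export
categorize_su <- function(su, genes) {
  if (nrow(su) == 0) {
    return(tibble::tibble(subtype = character(0), category = character(0),
                          n = integer(0), gene_ids = list()))
  }
  su |>
    dplyr::left_join(genes[, c("gene_id", "category")], by = "gene_id") |>
    dplyr::mutate(category = ifelse(is.na(.data$category), "other",
                                    .data$category)) |>
    dplyr::group_by(.data$subtype, .data$category) |>
    dplyr::summarise(n = dplyr::n(), gene_ids = list(.data$gene_id),
                     .groups = "drop")
}
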