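#' EM isoform-proportion estimate for one set of compatibility classes
#'
#' Low-level solver behind [estimate_psi()]. Reads are grouped into
#' compatibility classes (sets of isoforms a read is consistent with).
#' Under the generative model a read comes from isoform `i` with
#' probability proportional to `psi_i * length_i`, so the EM iterates on
#' the read-fraction parameters `theta_i` (proportional to
#' `psi_i * length_i`): the E-step distributes each class's reads over its
#' isoforms proportionally to `theta`, the M-step re-estimates `theta` as
#' the mean responsibility, and the final `theta` is converted to
#' transcript proportions by dividing by isoform length and renormalizing.
#' The observed-data log-likelihood is non-decreasing at every iteration.
#'
#' @param class_counts Integer vector: reads per compatibility class.
#' @param class_sets List of integer vectors: the isoform indices (into
#'   `lengths`) each class is compatible with.
#' @param lengths Positive isoform lengths in bp.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return List with `psi`, `theta`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`.
#' @export
psi_em <- function(class_counts, class_sets, lengths,
                   tol = 1e-10, max_iter = 2000) {
  k <- length(lengths)
  if (k < 1 || any(lengths <= 0)) {
    stop_atlas("lengths must be positive", "validation")
  }
  if (length(class_counts) != length(class_sets)) {
    stop_atlas("class_counts and class_sets must align", "validation")
  }
  if (any(lengths(class_sets) == 0)) {
    stop_atlas("compatibility class with no isoforms", "data")
  }
  n <- sum(class_counts)
  if (n < 1) stop_atlas("need at least one read", "data")
  theta <- rep(1 / k, k)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    class_mass <- vapply(class_sets, function(s) sum(theta[s]), 0)
    ll <- sum(class_counts * log(class_mass))
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    new_theta <- numeric(k)
    for (c_i in seq_along(class_sets)) {
      s <- class_sets[[c_i]]
      new_theta[s] <- new_theta[s] +
        class_counts[c_i] * theta[s] / class_mass[c_i]
    }
    theta <- new_theta / n
  }
  psi <- (theta / lengths) / sum(theta / lengths)
  list(psi = psi, theta = theta, loglik = trace[length(trace)],
       loglik_trace = trace, iterations = iter, converged = converged)
}

# Collapse a compatibility triplet table to per (sample, gene) classes.
# Assumes ambiguous reads have one row per compatible isoform.
compat_classes <- function(compat, isoforms) {
  bad <- !compat$isoform_id %in% isoforms$isoform_id
  if (any(bad)) {
    stop_atlas(sprintf("read(s) compatible with unknown isoform(s), e.g. %s",
                       compat$read_id[which(bad)[1]]), "data")
  }
  compat$gene_id <- isoforms$gene_id[match(compat$isoform_id,
                                           isoforms$isoform_id)]
  # per-read signature; most reads are unambiguous, so handle the single-row
  # majority vectorized and paste only the rest
  nrep <- dplyr::add_count(compat, .data$sample_id, .data$read_id,
                           name = ".n_compat")
  uni <- nrep[nrep$.n_compat == 1, ]
  multi <- nrep[nrep$.n_compat > 1, ]
  sig_uni <- tibble::tibble(sample_id = uni$sample_id, gene_id = uni$gene_id,
                            signature = uni$isoform_id)
  sig_multi <- if (nrow(multi) > 0) {
    multi |>
      dplyr::group_by(.data$sample_id, .data$gene_id, .data$read_id) |>
      dplyr::summarise(signature = paste(sort(.data$isoform_id),
                                         collapse = "\t"),
                       .groups = "drop") |>
      dplyr::select("sample_id", "gene_id", "signature")
  } else {
    sig_uni[0, ]
  }
  dplyr::bind_rows(sig_uni, sig_multi) |>
    dplyr::count(.data$sample_id, .data$gene_id, .data$signature,
                 name = "n_reads")
}

#' Estimate per-isoform PSI for every sample and gene
#'
#' Groups the read-isoform compatibility records into compatibility
#' classes and runs the EM of [psi_em()] per (sample, gene), yielding the
#' percent-spliced-in (PSI) vector: the estimated proportion of the gene's
#' transcripts attributable to each isoform. Genes with no reads in a
#' sample are omitted for that sample.
#'
#' @param compat Compatibility tibble (`sample_id`, `read_id`,
#'   `isoform_id`; one row per compatible pairing).
#' @param isoforms Isoform catalog tibble (`gene_id`, `isoform_id`,
#'   `length_bp`, `group`).
#' @param tol,max_iter EM control parameters passed to [psi_em()].
#' @return A tibble (`sample_id`, `gene_id`, `isoform_id`, `psi`); each
#'   (sample, gene) PSI vector sums to 1.
#' @export
estimate_psi <- function(compat, isoforms, tol = 1e-10, max_iter = 2000) {
  classes <- compat_classes(compat, isoforms)
  iso_split <- split(seq_len(nrow(isoforms)), isoforms$gene_id)
  out <- classes |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::group_map(function(df, key) {
      rows <- iso_split[[key$gene_id]]
      iso_ids <- isoforms$isoform_id[rows]
      lens <- isoforms$length_bp[rows]
      sets <- lapply(strsplit(df$signature, "\t", fixed = TRUE),
                     function(ids) match(ids, iso_ids))
      fit <- psi_em(df$n_reads, sets, lens, tol = tol, max_iter = max_iter)
      tibble::tibble(sample_id = key$sample_id, gene_id = key$gene_id,
                     isoform_id = iso_ids, psi = fit$psi)
    }) |>
    dplyr::bind_rows()
  out
}

#' Replicate-averaged PSI per subtype
#'
#' @param psi Per-sample PSI tibble from [estimate_psi()].
#' @param samples Sample sheet tibble.
#' @return A tibble (`subtype`, `gene_id`, `isoform_id`, `psi`,
#'   `n_replicates`), with `psi` the mean over the replicates in which the
#'   gene was quantified.
#' @export
psi_by_subtype <- function(psi, samples) {
  psi |>
    dplyr::left_join(samples[, c("sample_id", "subtype")], by = "sample_id") |>
    dplyr::group_by(.data$subtype, .data$gene_id, .data$isoform_id) |>
    dplyr::summarise(psi = mean(.data$psi),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Determine the major isoform per subtype with replicate agreement
#'
#' The major isoform of a gene in a subtype is the isoform with the
#' highest PSI in *each* biological replicate. If the top isoform differs
#' between replicates, if any replicate has an exact tie at the top, or if
#' the gene was not quantified in every replicate of the subtype, the
#' major isoform is undefined (`NA`) and the gene is excluded from
#' switch analyses for that subtype.
#'
#' @param psi Per-sample PSI tibble from [estimate_psi()].
#' @param samples Sample sheet tibble.
#' @return A tibble (`subtype`, `gene_id`, `major_isoform`).
#' @export
major_isoform <- function(psi, samples) {
  ann <- dplyr::left_join(psi, samples[, c("sample_id", "subtype")],
                          by = "sample_id")
  if (anyNA(ann$subtype)) {
    stop_atlas("PSI table contains samples missing from the sample sheet",
               "config")
  }
  n_rep <- samples |>
    dplyr::count(.data$subtype, name = "n_expected")
  per_rep <- ann |>
    dplyr::group_by(.data$subtype, .data$sample_id, .data$gene_id) |>
    dplyr::summarise(
      top = .data$isoform_id[which.max(.data$psi)],
      tied = sum(.data$psi == max(.data$psi)) > 1,
      .groups = "drop"
    )
  per_rep |>
    dplyr::group_by(.data$subtype, .data$gene_id) |>
    dplyr::summarise(
      n_have = dplyr::n(),
      agree = dplyr::n_distinct(.data$top) == 1 && !any(.data$tied),
      top = .data$top[1],
      .groups = "drop"
    ) |>
    dplyr::left_join(n_rep, by = "subtype") |>
    dplyr::mutate(major_isoform = ifelse(
      .data$agree & .data$n_have == .data$n_expected, .data$top, NA_character_
    )) |>
    dplyr::select("subtype", "gene_id", "major_isoform")
}

#' Min-ratio switching fold change
#'
#' For a gene whose major isoform differs between subtypes A and B, the
#' expression ratio in each subtype is the PSI of that subtype's major
#' isoform divided by the PSI of the other subtype's major isoform; the
#' switching fold change is the minimum of the two ratios. A zero
#' denominator yields `Inf` with a flag.
#'
#' @param psi_a,psi_b Named PSI vectors (names are isoform ids) for the
#'   two subtypes.
#' @param major_a,major_b The two (distinct) major isoform ids.
#' @return A one-row tibble (`ratio_a`, `ratio_b`, `fold`, `two_fold`,
#'   `infinite_fold`).
#' @export
#' @examples
#' switch_fold_change(c(i1 = 0.8, i2 = 0.2), c(i1 = 0.2, i2 = 0.8),
#'                    "i1", "i2") # fold = 4
switch_fold_change <- function(psi_a, psi_b, major_a, major_b) {
  if (identical(major_a, major_b)) {
    stop_atlas("major isoforms must differ", "validation")
  }
  ratio_a <- unname(psi_a[major_a] / psi_a[major_b])
  ratio_b <- unname(psi_b[major_b] / psi_b[major_a])
  if (anyNA(c(ratio_a, ratio_b))) {
    stop_atlas("major isoforms absent from PSI vectors", "validation")
  }
  fold <- min(ratio_a, ratio_b)
  tibble::tibble(ratio_a = ratio_a, ratio_b = ratio_b, fold = fold,
                 two_fold = fold >= 2, infinite_fold = !is.finite(fold))
}

#' Detect transcript-switching genes between subtype pairs
#'
#' A switch event requires, for a subtype pair (A, B): a defined major
#' isoform in both subtypes that differs between them; no significant
#' gene-level differential expression for that pair
#' (`padj > padj_max`; untestable genes fail); and expression class INT or
#' HE in both subtypes (NE/LE genes are discounted). Fold changes come
#' from [switch_fold_change()] on the replicate-mean subtype PSI vectors.
#'
#' @param psi Per-sample PSI tibble from [estimate_psi()].
#' @param samples Sample sheet tibble.
#' @param de Pairwise DE table from [pairwise_de()].
#' @param classes Class assignments from [assign_classes()].
#' @param padj_max DE significance threshold (default 0.01).
#' @return A tibble (`subtype_a`, `subtype_b`, `gene_id`, `major_a`,
#'   `major_b`, `ratio_a`, `ratio_b`, `fold`, `two_fold`).
#' @export
detect_switches <- function(psi, samples, de, classes, padj_max = 0.01) {
  majors <- major_isoform(psi, samples)
  mean_psi <- psi_by_subtype(psi, samples)
  subtypes <- unique(samples$subtype)
  pairs <- utils::combn(subtypes, 2, simplify = FALSE)
  expressed <- classes[classes$class %in% c("INT", "HE"), ]

  purrr::map(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    ma <- majors[majors$subtype == a & !is.na(majors$major_isoform), ]
    mb <- majors[majors$subtype == b & !is.na(majors$major_isoform), ]
    cand <- dplyr::inner_join(
      ma[, c("gene_id", "major_isoform")],
      mb[, c("gene_id", "major_isoform")],
      by = "gene_id", suffix = c("_a", "_b")
    )
    cand <- cand[cand$major_isoform_a != cand$major_isoform_b, ]
    if (nrow(cand) == 0) return(NULL)
    # not significantly DE in this pair
    de_pair <- de[(de$subtype_a == a & de$subtype_b == b) |
                    (de$subtype_a == b & de$subtype_b == a), ]
    padj <- de_pair$padj[match(cand$gene_id, de_pair$gene_id)]
    cand <- cand[!is.na(padj) & padj > padj_max, ]
    # expressed (INT/HE) in both subtypes
    cand <- cand[cand$gene_id %in% expressed$gene_id[expressed$subtype == a] &
                   cand$gene_id %in% expressed$gene_id[expressed$subtype == b], ]
    if (nrow(cand) == 0) return(NULL)
    purrr::map(seq_len(nrow(cand)), function(i) {
      g <- cand$gene_id[i]
      pa <- mean_psi[mean_psi$subtype == a & mean_psi$gene_id == g, ]
      pb <- mean_psi[mean_psi$subtype == b & mean_psi$gene_id == g, ]
      fc <- switch_fold_change(setNames(pa$psi, pa$isoform_id),
                               setNames(pb$psi, pb$isoform_id),
                               cand$major_isoform_a[i],
                               cand$major_isoform_b[i])
      tibble::tibble(subtype_a = a, subtype_b = b, gene_id = g,
                     major_a = cand$major_isoform_a[i],
                     major_b = cand$major_isoform_b[i],
                     ratio_a = fc$ratio_a, ratio_b = fc$ratio_b,
                     fold = fc$fold, two_fold = fc$two_fold)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Sum PSI within isoform groups
#'
#' Aggregates PSI over the catalog's isoform group labels (functional,
#' truncated, non-coding) for each gene within each sample or subtype,
#' whichever unit the input table carries. Grouped PSI vectors sum to 1.
#'
#' @param psi PSI tibble from [estimate_psi()] or [psi_by_subtype()].
#' @param isoforms Isoform catalog with a `group` column.
#' @return A tibble with the input's unit columns plus `group` and `psi`.
#' @export
group_psi <- function(psi, isoforms) {
  grp <- isoforms$group[match(psi$isoform_id, isoforms$isoform_id)]
  if (anyNA(grp)) {
    missing <- unique(psi$isoform_id[is.na(grp)])
    stop_atlas(sprintf("isoform(s) without a group label: %s",
                       paste(head(missing, 5), collapse = ", ")), "annotation")
  }
  unit_cols <- intersect(c("sample_id", "subtype", "gene_id"), names(psi))
  psi$group <- grp
  psi |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(unit_cols, "group")))) |>
    dplyr::summarise(psi = sum(.data$psi), .groups = "drop")
}
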