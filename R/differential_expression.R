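# Helpers shared by the DE operations ---------------------------------------

# Validate a pair request and return list(a = ids, b = ids) of sample ids.
pair_samples <- function(samples, pair) {
  if (length(pair) != 2 || anyDuplicated(pair)) {
    stop_atlas("pair must name two distinct subtypes", "config")
  }
  groups <- subtype_samples(samples)
  for (st in pair) {
    if (!st %in% names(groups)) {
      stop_atlas(sprintf("subtype '%s' missing from sample sheet", st), "config")
    }
    if (length(groups[[st]]) < 2) {
      stop_atlas(sprintf("subtype '%s' has fewer than 2 replicates", st),
                 "config")
    }
  }
  list(a = groups[[pair[1]]], b = groups[[pair[2]]])
}

norm_group <- function(m, sf, ids) {
  s <- sf$size_factor[match(ids, sf$sample_id)]
  if (anyNA(s)) stop_atlas("size factors missing for some samples", "validation")
  list(q = sweep(m[, ids, drop = FALSE], 2, s, `/`), s = s)
}

#' Per-gene method-of-moments NB dispersion for one subtype pair
#'
#' Estimates a per-gene negative-binomial dispersion from the
#' size-factor-normalized counts of the two groups:
#' `alpha = max(0, (v - m) / m^2)` floored at `1e-8`, where `m` is the
#' pooled mean of the normalized counts and `v` the pooled within-group
#' variance. Genes with zero counts in every sample of both groups are
#' flagged untestable (`NA` dispersion).
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet tibble.
#' @param pair Character vector of two subtype names `(A, B)`.
#' @param sf Size factors ([size_factors()]); computed from `counts` when
#'   `NULL`.
#' @return A tibble (`gene_id`, `base_mean`, `dispersion_raw`, `dispersion`,
#'   `testable`). `dispersion_raw` is the unfloored moment estimate used
#'   for trend fitting by [moderate_dispersion()].
#' @export
estimate_dispersion <- function(counts, samples, pair, sf = NULL) {
  m <- check_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  ids <- pair_samples(samples, pair)
  ga <- norm_group(m, sf, ids$a)
  gb <- norm_group(m, sf, ids$b)
  qa <- ga$q; qb <- gb$q
  na <- ncol(qa); nb <- ncol(qb)
  mean_all <- rowSums(cbind(qa, qb)) / (na + nb)
  ss <- rowSums((qa - rowMeans(qa))^2) + rowSums((qb - rowMeans(qb))^2)
  v <- ss / (na + nb - 2)
  testable <- rowSums(m[, c(ids$a, ids$b), drop = FALSE]) > 0
  raw <- ifelse(testable, (v - mean_all) / mean_all^2, NA_real_)
  disp <- pmax(pmax(raw, 0), 1e-8)
  disp[!testable] <- NA_real_
  tibble::tibble(gene_id = rownames(m), base_mean = unname(mean_all),
                 dispersion_raw = unname(raw), dispersion = unname(disp),
                 testable = unname(testable))
}

#' Moderate per-gene dispersions with a mean-dispersion trend
#'
#' With two replicates per group the per-gene moment estimate has so few
#' degrees of freedom that plugging it into a Wald test is strongly
#' anti-conservative. Sharing information across genes restores
#' calibration: the unfloored moment estimates are averaged in quantile
#' bins of the mean, smoothed (loess on log mean), and each gene's working
#' dispersion becomes the maximum of its own floored estimate and the
#' trend value at its mean.
#'
#' @param disp Output of [estimate_dispersion()].
#' @return `disp` with columns `trend` and `dispersion_use` added.
#' @export
moderate_dispersion <- function(disp) {
  ok <- disp$testable & is.finite(disp$dispersion_raw)
  n_ok <- sum(ok)
  trend <- rep(NA_real_, nrow(disp))
  if (n_ok == 0) {
    disp$trend <- trend
    disp$dispersion_use <- disp$dispersion
    return(disp)
  }
  m <- disp$base_mean[ok]
  a <- disp$dispersion_raw[ok]
  n_bins <- max(1, min(20, floor(n_ok / 25)))
  if (n_bins < 2) {
    tr <- rep(max(mean(a), 1e-8), n_ok)
  } else {
    bins <- cut(rank(m, ties.method = "first"), n_bins, labels = FALSE)
    bm <- tapply(m, bins, mean)
    ba <- tapply(a, bins, mean)
    sm <- if (n_bins >= 5) {
      fitted(loess(ba ~ log(bm), span = 1))
    } else {
      ba
    }
    tr <- approx(log(bm), sm, xout = log(m), rule = 2)$y
    tr <- pmax(tr, 1e-8)
  }
  trend[ok] <- tr
  disp$trend <- trend
  disp$dispersion_use <- pmax(disp$dispersion, trend)
  disp$dispersion_use[!disp$testable] <- NA_real_
  disp
}

#' Negative-binomial Wald test for one subtype pair
#'
#' For each gene, compares the mean size-factor-normalized counts of the
#' two groups. A pseudocount of 0.5 is added to each group mean before the
#' log, giving finite fold changes for one-sided zeros. The variance of a
#' normalized count is modeled as `m/s_j + alpha * m^2`; the group-mean
#' variance follows by averaging, and the delta method converts it to a
#' standard error of the log2 mean. The Wald statistic is the log2 fold
#' change `log2(m_B) - log2(m_A)` divided by the pooled standard error,
#' referred to the standard normal.
#'
#' @inheritParams estimate_dispersion
#' @param dispersion Per-gene dispersions to use: a tibble with `gene_id`
#'   and a `dispersion_use` (preferred) or `dispersion` column, e.g. from
#'   [moderate_dispersion()]; computed (with moderation) when `NULL`.
#' @return A tibble (`gene_id`, `subtype_a`, `subtype_b`, `base_mean`,
#'   `log2fc`, `se`, `wald`, `p`). Genes with zero counts throughout both
#'   groups get `NA` statistics and are excluded from multiple-testing
#'   correction downstream.
#' @export
nb_wald_test <- function(counts, samples, pair, sf = NULL, dispersion = NULL) {
  m <- check_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- moderate_dispersion(estimate_dispersion(counts, samples,
                                                          pair, sf))
  }
  ids <- pair_samples(samples, pair)
  ga <- norm_group(m, sf, ids$a)
  gb <- norm_group(m, sf, ids$b)
  qa <- ga$q; qb <- gb$q
  na <- ncol(qa); nb <- ncol(qb)

  dcol <- if ("dispersion_use" %in% names(dispersion)) "dispersion_use" else "dispersion"
  alpha <- dispersion[[dcol]][match(rownames(m), dispersion$gene_id)]
  testable <- rowSums(m[, c(ids$a, ids$b), drop = FALSE]) > 0 & !is.na(alpha)

  m_a <- rowMeans(qa) + 0.5
  m_b <- rowMeans(qb) + 0.5
  var_a <- (m_a * sum(1 / ga$s) + na * alpha * m_a^2) / na^2
  var_b <- (m_b * sum(1 / gb$s) + nb * alpha * m_b^2) / nb^2
  se_a <- sqrt(var_a) / (m_a * log(2))
  se_b <- sqrt(var_b) / (m_b * log(2))
  log2fc <- log2(m_b) - log2(m_a)
  se <- sqrt(se_a^2 + se_b^2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))

  out <- tibble::tibble(
    gene_id = rownames(m), subtype_a = pair[1], subtype_b = pair[2],
    base_mean = unname((rowMeans(qa) * na + rowMeans(qb) * nb) / (na + nb)),
    log2fc = unname(log2fc), se = unname(se), wald = unname(wald),
    p = unname(p)
  )
  out[!testable, c("log2fc", "se", "wald", "p")] <- NA_real_
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR correction: p-values are sorted ascending, the i-th becomes
#' `min over k >= i of p_(k) * m / k` capped at 1, and results are returned
#' in input order. `NA` entries (untestable genes) are excluded from `m`
#' and stay `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.1)) # 0.03 0.03 0.10
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_atlas("p must be numeric", "validation")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_atlas("p-values must lie in [0, 1]", "validation")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' All pairwise differential expression tests
#'
#' Runs the moderated NB Wald test for every unordered pair of subtypes
#' (in sample-sheet order, so `log2fc > 0` means higher in `subtype_b`)
#' and applies Benjamini-Hochberg correction within each pair across
#' testable genes.
#'
#' @inheritParams estimate_dispersion
#' @return A tibble with one row per (gene, pair): `gene_id`, `subtype_a`,
#'   `subtype_b`, `base_mean`, `log2fc`, `se`, `wald`, `p`, `padj`.
#' @export
pairwise_de <- function(counts, samples, sf = NULL) {
  groups <- subtype_samples(samples)
  if (length(groups) < 2) {
    stop_atlas("need at least two subtypes", "config")
  }
  if (any(lengths(groups) < 2)) {
    stop_atlas("every subtype needs at least 2 replicates", "config")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    disp <- moderate_dispersion(estimate_dispersion(counts, samples, pr, sf))
    res <- nb_wald_test(counts, samples, pr, sf, disp)
    res$padj <- bh_adjust(res$p)
    res
  }) |> dplyr::bind_rows()
}

#' Count significant genes per pair at fold-change cutoffs
#'
#' For every subtype pair and fold-change cutoff `c`, counts genes with
#' `padj <= padj_max` and `|log2fc| >= log2(c)`; a cutoff of zero imposes
#' no fold-change filter.
#'
#' @param de Output of [pairwise_de()].
#' @param padj_max Significance threshold on adjusted p-values.
#' @param fc_cutoffs Strictly increasing fold-change cutoffs (linear scale).
#' @return A tibble (`subtype_a`, `subtype_b`, `cutoff`, `n`).
#' @export
count_de <- function(de, padj_max = 0.01, fc_cutoffs = c(0, 2, 5)) {
  if (any(diff(fc_cutoffs) <= 0)) {
    stop_atlas("fc_cutoffs must be strictly increasing", "validation")
  }
  purrr::map(fc_cutoffs, function(cf) {
    thr <- log2(cf) # cf = 0 gives -Inf: no fold-change filter
    de |>
      dplyr::group_by(.data$subtype_a, .data$subtype_b) |>
      dplyr::summarise(
        cutoff = cf,
        n = sum(!is.na(.data$padj) & .data$padj <= padj_max &
                  abs(.data$log2fc) >= thr),
        .groups = "drop"
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$subtype_a, .data$subtype_b, .data$cutoff)
}
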