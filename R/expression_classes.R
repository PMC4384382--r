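#' Fit a two-component Gaussian mixture to log2 expression by EM
#'
#' Expressed genes in bulk RNA-seq show a characteristic bimodal log
#' expression distribution: a shoulder of lowly expressed (LE) genes and a
#' peak of highly expressed (HE) genes. This fits a two-component
#' univariate Gaussian mixture by expectation-maximization. Initialization
#' is deterministic: the data are split at the median and each half
#' provides its component's starting moments. Components are returned
#' ordered so that `mu_le < mu_he`.
#'
#' @param x Numeric vector of log2 normalized expression values from genes
#'   with nonzero counts (finite, length >= 20).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `"mixture_fit"`: a list with `mu_le`,
#'   `sd_le`, `mu_he`, `sd_he`, `weight_he`, `loglik_trace` (non-decreasing),
#'   `converged`, `iterations`, `n` and the input `data`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 1), rnorm(500, 8))
#' fit <- fit_expression_mixture(x)
#' tidy(fit)
fit_expression_mixture <- function(x, tol = 1e-8, max_iter = 1000) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_atlas("x must be a finite numeric vector", "validation")
  }
  n <- length(x)
  if (n < 20) {
    stop_atlas(sprintf("need at least 20 values to fit a mixture (got %d)", n),
               "insufficient_data")
  }
  xs <- sort(x)
  lo <- xs[seq_len(floor(n / 2))]
  hi <- xs[(floor(n / 2) + 1):n]
  mu <- c(mean(lo), mean(hi))
  sd_ <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-3)
  if (anyNA(sd_)) sd_ <- c(1, 1)
  w <- c(0.5, 0.5)

  loglik <- function(mu, sd_, w) {
    sum(log(w[1] * dnorm(x, mu[1], sd_[1]) + w[2] * dnorm(x, mu[2], sd_[2])))
  }
  trace <- loglik(mu, sd_, w)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d1 <- w[1] * dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    v1 <- sum(r1 * (x - mu[1])^2) / n1
    v2 <- sum(r2 * (x - mu[2])^2) / n2
    if (min(v1, v2) < 1e-6) {
      stop_atlas("degenerate component variance (< 1e-6) during EM", "fit")
    }
    sd_ <- sqrt(c(v1, v2))
    w <- c(n1, n2) / n
    ll <- loglik(mu, sd_, w)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  ord <- order(mu)
  structure(
    list(mu_le = mu[ord[1]], sd_le = sd_[ord[1]],
         mu_he = mu[ord[2]], sd_he = sd_[ord[2]],
         weight_he = w[ord[2]],
         loglik_trace = trace, converged = converged, iterations = iter,
         n = n, data = x),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component Gaussian mixture (n = %d, %s after %d iterations)\n",
    x$n, if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  LE: N(%.3f, %.3f^2)  weight %.3f\n", x$mu_le, x$sd_le,
              1 - x$weight_he))
  cat(sprintf("  HE: N(%.3f, %.3f^2)  weight %.3f\n", x$mu_he, x$sd_he,
              x$weight_he))
  invisible(x)
}

# Posterior probability of the LE component at x under a mixture fit,
# computed via log densities for stability far in the tails.
posterior_le <- function(fit, x) {
  l1 <- log(1 - fit$weight_he) + dnorm(x, fit$mu_le, fit$sd_le, log = TRUE)
  l2 <- log(fit$weight_he) + dnorm(x, fit$mu_he, fit$sd_he, log = TRUE)
  1 / (1 + exp(l2 - l1))
}

#' FDR-based class boundaries from a mixture fit
#'
#' Computes the two log2 expression thresholds that separate the LE,
#' intermediate (INT) and HE classes at a given false discovery rate. The
#' upper boundary `b_high` is the smallest expression value at which the
#' posterior probability of the LE component drops to `alpha` (so HE calls
#' carry at most `alpha` LE contamination); the lower boundary `b_low` is
#' the largest value at which the posterior probability of the HE component
#' is at most `alpha`. If a posterior never crosses `alpha` (heavily
#' overlapping components) the corresponding boundary is set to +/-Inf with
#' a warning, which yields an INT-dominated classification.
#'
#' @param fit A [fit_expression_mixture()] result.
#' @param alpha FDR level (default 0.01).
#' @return A one-row tibble with `alpha`, `b_low`, `b_high` and
#'   `boundary_warning`.
#' @export
class_boundaries <- function(fit, alpha = 0.01) {
  if (!inherits(fit, "mixture_fit")) {
    stop_atlas("fit must be a mixture_fit", "validation")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_atlas("alpha must lie in (0, 1)", "validation")
  }
  span <- 10 * max(fit$sd_le, fit$sd_he)
  lo <- fit$mu_le - span
  hi <- fit$mu_he + span
  grid <- seq(lo, hi, length.out = 4096)
  p_le <- posterior_le(fit, grid)
  warn_flag <- FALSE

  # b_high: smallest x with P(LE | x) <= alpha.
  idx <- which(p_le <= alpha)
  if (length(idx) == 0) {
    b_high <- Inf
    warn_flag <- TRUE
  } else if (idx[1] == 1) {
    b_high <- grid[1]
  } else {
    i <- idx[1]
    b_high <- uniroot(function(z) posterior_le(fit, z) - alpha,
                      c(grid[i - 1], grid[i]), tol = 1e-10)$root
  }

  # b_low: largest x with P(HE | x) <= alpha, i.e. P(LE | x) >= 1 - alpha.
  idx <- which(p_le >= 1 - alpha)
  if (length(idx) == 0) {
    b_low <- -Inf
    warn_flag <- TRUE
  } else if (idx[length(idx)] == length(grid)) {
    b_low <- grid[length(grid)]
  } else {
    i <- idx[length(idx)]
    b_low <- uniroot(function(z) posterior_le(fit, z) - (1 - alpha),
                     c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }
  if (warn_flag) {
    warn("posterior never crosses alpha; boundary set to +/-Inf")
  }
  tibble::tibble(alpha = alpha, b_low = b_low, b_high = b_high,
                 boundary_warning = warn_flag)
}

#' Fit per-subtype expression mixtures and class boundaries
#'
#' For each subtype, averages normalized expression over its replicates,
#' drops genes with zero counts in every replicate, fits the two-component
#' mixture to the log2 values and derives FDR class boundaries.
#'
#' @param norm Normalized expression (wide tibble from
#'   [normalize_counts()]).
#' @param samples Sample sheet tibble (`sample_id`, `subtype`).
#' @param alpha FDR level for the class boundaries.
#' @param per_sample If `TRUE`, fit on individual samples' values rather
#'   than replicate means (boundaries are still per subtype).
#' @return A tibble with one row per subtype: mixture parameters,
#'   `b_low`, `b_high`, plus a `fit` list-column of `"mixture_fit"` objects.
#' @export
fit_subtype_mixtures <- function(norm, samples, alpha = 0.01,
                                 per_sample = FALSE) {
  m <- as_gene_matrix(norm)
  groups <- subtype_samples(samples)
  missing <- setdiff(unlist(groups), colnames(m))
  if (length(missing) > 0) {
    stop_atlas(sprintf("samples missing from expression matrix: %s",
                       paste(missing, collapse = ", ")), "config")
  }
  purrr::map(names(groups), function(st) {
    sub <- m[, groups[[st]], drop = FALSE]
    vals <- if (per_sample) {
      v <- as.vector(sub)
      v[v > 0]
    } else {
      v <- rowMeans(sub)
      v[v > 0]
    }
    fit <- fit_expression_mixture(log2(vals))
    b <- class_boundaries(fit, alpha)
    tibble::tibble(
      subtype = st,
      mu_le = fit$mu_le, sd_le = fit$sd_le,
      mu_he = fit$mu_he, sd_he = fit$sd_he,
      weight_he = fit$weight_he, converged = fit$converged,
      alpha = b$alpha, b_low = b$b_low, b_high = b$b_high,
      fit = list(fit)
    )
  }) |> dplyr::bind_rows()
}

#' Assign NE/LE/INT/HE expression classes
#'
#' Per subtype, a gene's replicate-mean normalized expression determines
#' its class: zero in every replicate gives NE (not expressed); otherwise
#' the log2 mean is compared with the subtype's FDR boundaries — below
#' `b_low` gives LE, above `b_high` gives HE, and values between the
#' boundaries give INT. The four classes partition all genes.
#'
#' @param norm Normalized expression (wide tibble).
#' @param samples Sample sheet tibble.
#' @param fits Per-subtype fits from [fit_subtype_mixtures()] (must carry
#'   `subtype`, `b_low`, `b_high`).
#' @return A long tibble (`gene_id`, `subtype`, `class`) with `class` a
#'   factor with levels NE, LE, INT, HE.
#' @export
assign_classes <- function(norm, samples, fits) {
  m <- as_gene_matrix(norm)
  groups <- subtype_samples(samples)
  if (!all(names(groups) %in% fits$subtype)) {
    stop_atlas("fits missing for some subtypes", "config")
  }
  purrr::map(names(groups), function(st) {
    sub <- m[, groups[[st]], drop = FALSE]
    mu <- rowMeans(sub)
    b <- fits[fits$subtype == st, ]
    lg <- log2(mu)
    cls <- dplyr::case_when(
      mu == 0 ~ "NE",
      lg < b$b_low ~ "LE",
      lg > b$b_high ~ "HE",
      .default = "INT"
    )
    tibble::tibble(gene_id = rownames(m), subtype = st,
                   class = factor(cls, levels = c("NE", "LE", "INT", "HE")))
  }) |> dplyr::bind_rows()
}
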