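#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture fit into one row per component
#'
#' @param x A `"mixture_fit"`.
#' @param ... Unused.
#' @return A tibble (`component`, `mean`, `sd`, `weight`).
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    component = c("LE", "HE"),
    mean = c(x$mu_le, x$mu_he),
    sd = c(x$sd_le, x$sd_he),
    weight = c(1 - x$weight_he, x$weight_he)
  )
}

#' One-row summary of a mixture fit
#'
#' @param x A `"mixture_fit"`.
#' @param ... Unused.
#' @return A tibble (`loglik`, `iterations`, `converged`, `n`).
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik_trace[length(x$loglik_trace)],
    iterations = x$iterations, converged = x$converged, n = x$n
  )
}

#' Tidy PCA scores into long format
#'
#' @param x An `"atlas_pca"`.
#' @param ... Unused.
#' @return A long tibble (`sample_id`, `component`, `score`, optional
#'   `subtype`).
#' @export
tidy.atlas_pca <- function(x, ...) {
  keep <- intersect(c("sample_id", "subtype"), names(x$scores))
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score") |>
    dplyr::select(dplyr::all_of(keep), "component", "score")
}

#' One-row summary of a PCA
#'
#' @param x An `"atlas_pca"`.
#' @param ... Unused.
#' @return A tibble with sample count and the variance fractions of the
#'   first two components.
#' @export
glance.atlas_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$explained),
    pc1_fraction = x$explained[1],
    pc2_fraction = if (length(x$explained) >= 2) x$explained[2] else NA_real_
  )
}
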