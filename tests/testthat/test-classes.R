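make_fit <- function(mu_le, sd_le, mu_he, sd_he, weight_he) {
  structure(list(mu_le = mu_le, sd_le = sd_le, mu_he = mu_he, sd_he = sd_he,
                 weight_he = weight_he, loglik_trace = 0, converged = TRUE,
                 iterations = 1, n = 100, data = numeric(0)),
            class = "mixture_fit")
}

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(2024)
  x <- c(rnorm(2500, 1, 1), rnorm(2500, 8, 1))
  fit <- fit_expression_mixture(x)
  expect_lt(abs(fit$mu_le - 1), 0.15)
  expect_lt(abs(fit$mu_he - 8), 0.15)
  expect_lt(abs(fit$weight_he - 0.5), 0.03)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_lt(fit$mu_le, fit$mu_he)

  # independent cross-check against a reference GMM implementation
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust looks this up in the caller
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(ref$parameters$mean)),
               c(fit$mu_le, fit$mu_he), tolerance = 0.05)
})

test_that("log-likelihood trace is non-decreasing on assorted inputs", {
  set.seed(5)
  inputs <- list(
    rnorm(200), c(rnorm(100, 0, 0.5), rnorm(300, 4, 2)),
    rexp(500), runif(100, -3, 3)
  )
  for (x in inputs) {
    fit <- fit_expression_mixture(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("single-component input stays usable and yields INT-dominated classes", {
  set.seed(8)
  x <- rnorm(1000, 5, 1)
  fit <- fit_expression_mixture(x)
  expect_s3_class(fit, "mixture_fit")
  b <- suppressWarnings(class_boundaries(fit, 0.01))
  expect_lte(b$b_low, b$b_high)
  # overlapping components put the bulk of the data between the boundaries
  frac_int <- mean(x >= b$b_low & x <= b$b_high)
  expect_gt(frac_int, 0.5)

  # boundaries that never cross alpha classify every expressed gene as INT
  norm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         a = c(0, 2, 50), b = c(0, 3, 60))
  samples <- tibble::tibble(sample_id = c("a", "b"),
                            subtype = "T", replicate = 1:2)
  fits <- tibble::tibble(subtype = "T", b_low = -Inf, b_high = Inf)
  cls <- assign_classes(norm, samples, fits)
  expect_equal(as.character(cls$class), c("NE", "INT", "INT"))
})

test_that("boundaries respect symmetry and the alpha = 0.5 midpoint", {
  fit <- make_fit(-2, 1, 2, 1, 0.5)
  b <- class_boundaries(fit, 0.01)
  expect_true(is.finite(b$b_low) && is.finite(b$b_high))
  expect_equal(b$b_low, -b$b_high, tolerance = 1e-6)
  b5 <- class_boundaries(fit, 0.5)
  expect_equal(b5$b_low, 0, tolerance = 1e-6)
  expect_equal(b5$b_high, 0, tolerance = 1e-6)
  # analytic crossing of the posterior for equal unit-sd components
  expect_equal(b$b_high, log(99) / 4, tolerance = 1e-6)
})

test_that("boundaries bracket the midpoint of a recovered mixture", {
  set.seed(2024)
  x <- c(rnorm(2500, 1, 1), rnorm(2500, 8, 1))
  fit <- fit_expression_mixture(x)
  b <- class_boundaries(fit, 0.01)
  expect_lt(b$b_low, 4.5)
  expect_gt(b$b_high, 4.5)
  # numeric check against the posterior curve itself
  expect_equal(posterior_le(fit, b$b_high), 0.01, tolerance = 1e-6)
  expect_equal(1 - posterior_le(fit, b$b_low), 0.01, tolerance = 1e-6)
})

test_that("lowering alpha widens the intermediate band", {
  fit <- make_fit(1, 1.2, 8, 0.9, 0.55)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  bs <- lapply(alphas, function(a) class_boundaries(fit, a))
  b_low <- vapply(bs, function(b) b$b_low, 0)
  b_high <- vapply(bs, function(b) b$b_high, 0)
  expect_true(all(diff(b_low) <= 1e-9))
  expect_true(all(diff(b_high) >= -1e-9))
  expect_true(all(b_low <= b_high))
})

test_that("insufficient or degenerate data raise classed errors", {
  expect_error(fit_expression_mixture(rnorm(10)),
               class = "cd4atlas_error_insufficient_data")
  expect_error(fit_expression_mixture(c(rep(0, 50), rep(5, 50))),
               class = "cd4atlas_error_fit")
  expect_error(fit_expression_mixture(c(1, NA, rep(2, 30))),
               class = "cd4atlas_error_validation")
})

test_that("classes partition genes and recover planted HE membership", {
  at <- small_atlas()
  fits <- fit_subtype_mixtures(at$norm, at$sim$samples)
  cls <- assign_classes(at$norm, at$sim$samples, fits)
  tab <- table(cls$subtype)
  expect_true(all(tab == nrow(at$sim$genes)))
  expect_false(anyNA(cls$class))

  comp <- at$sim$truth$planted_component
  joined <- dplyr::inner_join(cls, comp, by = c("gene_id", "subtype"))
  he <- joined[joined$component == "HE", ]
  expect_gte(mean(he$class == "HE"), 0.95)

  # NE definition: zero counts in every replicate
  m <- as.matrix(at$norm[-1])
  rownames(m) <- at$norm$gene_id
  groups <- split(at$sim$samples$sample_id, at$sim$samples$subtype)
  for (st in names(groups)) {
    zero <- rowSums(m[, groups[[st]], drop = FALSE]) == 0
    called_ne <- cls$gene_id[cls$subtype == st & cls$class == "NE"]
    expect_setequal(called_ne, rownames(m)[zero])
  }
})

test_that("assignments are invariant to gene order", {
  at <- small_atlas()
  fits <- fit_subtype_mixtures(at$norm, at$sim$samples)
  cls1 <- assign_classes(at$norm, at$sim$samples, fits)
  perm <- sample(nrow(at$norm))
  cls2 <- assign_classes(at$norm[perm, ], at$sim$samples, fits)
  j <- dplyr::inner_join(cls1, cls2, by = c("gene_id", "subtype"))
  expect_true(all(j$class.x == j$class.y))
})

test_that("parameter recovery is stable across repeated simulations", {
  errs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(2500, 1, 1), rnorm(2500, 8, 1))
    fit <- fit_expression_mixture(x)
    mean(abs(c(fit$mu_le - 1, fit$mu_he - 8)))
  })
  expect_lt(mean(errs), 0.1)
})
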