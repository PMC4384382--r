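psi_sheet <- function() {
  tibble::tibble(sample_id = c("A_r1", "A_r2", "B_r1", "B_r2"),
                 subtype = rep(c("A", "B"), each = 2), replicate = rep(1:2, 2))
}

test_that("EM reproduces length-corrected closed forms without ambiguity", {
  # equal lengths, unambiguous reads 30 and 70
  fit <- psi_em(c(30, 70), list(1L, 2L), c(1000, 1000))
  expect_equal(fit$psi, c(0.3, 0.7), tolerance = 1e-8)
  # lengths 1000 and 2000: psi = (0.3/1, 0.7/2) renormalized = (6/13, 7/13)
  fit2 <- psi_em(c(30, 70), list(1L, 2L), c(1000, 2000))
  expect_equal(fit2$psi, c(6 / 13, 7 / 13), tolerance = 1e-8)
  expect_lte(fit2$iterations, 3) # unambiguous data converge immediately
  # fully ambiguous reads, equal lengths: uniform fixed point
  fit3 <- psi_em(100, list(c(1L, 2L, 3L)), rep(800, 3))
  expect_equal(fit3$psi, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing on random class systems", {
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n_classes <- sample(2:6, 1)
    sets <- lapply(seq_len(n_classes), function(j) {
      sort(sample.int(k, sample(1:k, 1)))
    })
    counts <- rpois(n_classes, 50) + 1
    fit <- psi_em(counts, sets, runif(k, 500, 5000))
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(sum(fit$psi), 1, tolerance = 1e-9)
  }
})

test_that("estimate_psi validates compatibility against the catalog", {
  isoforms <- tibble::tibble(gene_id = "g1", isoform_id = c("g1.1", "g1.2"),
                             length_bp = c(1000L, 1000L),
                             group = c("functional", "truncated"))
  compat <- tibble::tibble(sample_id = "s1", read_id = c("r1", "r2"),
                           isoform_id = c("g1.1", "gX.9"))
  expect_error(estimate_psi(compat, isoforms), "r2",
               class = "cd4atlas_error_data")
  good <- tibble::tibble(sample_id = "s1",
                         read_id = c("r1", "r2", "r3", "r3"),
                         isoform_id = c("g1.1", "g1.2", "g1.1", "g1.2"))
  psi <- estimate_psi(good, isoforms)
  expect_equal(sum(psi$psi), 1, tolerance = 1e-9)
})

test_that("major isoform requires agreement across replicates without ties", {
  samples <- psi_sheet()
  base <- tidyr::expand_grid(sample_id = samples$sample_id,
                             isoform_id = c("g1.1", "g1.2")) |>
    dplyr::mutate(gene_id = "g1")
  agree <- dplyr::mutate(base, psi = rep(c(0.7, 0.3, 0.6, 0.4), 2))
  m <- major_isoform(agree, samples)
  expect_identical(m$major_isoform[m$subtype == "A"], "g1.1")

  disagree <- dplyr::mutate(base, psi = c(0.7, 0.3, 0.4, 0.6, 0.7, 0.3, 0.7, 0.3))
  m2 <- major_isoform(disagree, samples)
  expect_true(is.na(m2$major_isoform[m2$subtype == "A"]))
  expect_identical(m2$major_isoform[m2$subtype == "B"], "g1.1")

  tied <- dplyr::mutate(base, psi = c(0.5, 0.5, 0.7, 0.3, 0.7, 0.3, 0.7, 0.3))
  m3 <- major_isoform(tied, samples)
  expect_true(is.na(m3$major_isoform[m3$subtype == "A"]))

  # a replicate without quantification leaves the major undefined
  missing_rep <- agree[agree$sample_id != "A_r2", ]
  m4 <- major_isoform(missing_rep, samples)
  expect_true(is.na(m4$major_isoform[m4$subtype == "A"]))
})

test_that("switching fold change is the minimum of the two oriented ratios", {
  fc <- switch_fold_change(c(i1 = 0.8, i2 = 0.2), c(i1 = 0.2, i2 = 0.8),
                           "i1", "i2")
  expect_equal(fc$ratio_a, 4)
  expect_equal(fc$ratio_b, 4)
  expect_equal(fc$fold, 4)
  expect_true(fc$two_fold)

  fc2 <- switch_fold_change(c(i1 = 0.6, i2 = 0.4), c(i1 = 0.45, i2 = 0.55),
                            "i1", "i2")
  expect_equal(fc2$fold, min(0.6 / 0.4, 0.55 / 0.45), tolerance = 1e-12)
  expect_false(fc2$two_fold)

  # exact reversal gives equal ratios
  fc3 <- switch_fold_change(c(i1 = 0.65, i2 = 0.35), c(i1 = 0.35, i2 = 0.65),
                            "i1", "i2")
  expect_equal(fc3$ratio_a, fc3$ratio_b, tolerance = 1e-12)

  expect_error(switch_fold_change(c(i1 = 0.8, i2 = 0.2),
                                  c(i1 = 0.2, i2 = 0.8), "i1", "i1"),
               class = "cd4atlas_error_validation")
  inf <- switch_fold_change(c(i1 = 1, i2 = 0), c(i1 = 0, i2 = 1), "i1", "i2")
  expect_true(inf$infinite_fold)
  expect_identical(inf$fold, Inf)
})

test_that("DE and expression-class exclusions suppress switch events", {
  samples <- psi_sheet()
  psi <- tidyr::expand_grid(sample_id = samples$sample_id,
                            isoform_id = c("g1.1", "g1.2")) |>
    dplyr::mutate(gene_id = "g1",
                  psi = rep(c(0.8, 0.2, 0.8, 0.2, 0.2, 0.8, 0.2, 0.8)))
  de_row <- function(padj) {
    tibble::tibble(gene_id = "g1", subtype_a = "A", subtype_b = "B",
                   base_mean = 100, log2fc = 0, se = 1, wald = 0,
                   p = padj, padj = padj)
  }
  cls <- tidyr::expand_grid(gene_id = "g1", subtype = c("A", "B")) |>
    dplyr::mutate(class = factor("HE", levels = c("NE", "LE", "INT", "HE")))

  sw <- detect_switches(psi, samples, de_row(0.8), cls)
  expect_identical(nrow(sw), 1L)
  expect_equal(sw$fold, 4)

  # significantly DE in the pair: no event despite differing majors
  expect_identical(nrow(detect_switches(psi, samples, de_row(0.001), cls)), 0L)

  # LE class in one subtype: no event
  cls_le <- cls
  cls_le$class[cls_le$subtype == "A"] <- "LE"
  expect_identical(nrow(detect_switches(psi, samples, de_row(0.8), cls_le)), 0L)

  # untestable DE record also fails the not-DE requirement
  expect_identical(nrow(detect_switches(psi, samples, de_row(NA_real_), cls)), 0L)
})

test_that("grouped PSI sums within groups and conserves mass", {
  isoforms <- tibble::tibble(gene_id = "g1",
                             isoform_id = c("g1.1", "g1.2", "g1.3"),
                             length_bp = 1000L,
                             group = c("functional", "functional", "truncated"))
  psi <- tibble::tibble(subtype = "A", gene_id = "g1",
                        isoform_id = c("g1.1", "g1.2", "g1.3"),
                        psi = c(0.5, 0.3, 0.2))
  out <- group_psi(psi, isoforms)
  expect_equal(out$psi[out$group == "functional"], 0.8)
  expect_equal(out$psi[out$group == "truncated"], 0.2)
  expect_equal(sum(out$psi), 1, tolerance = 1e-9)

  single <- group_psi(psi[1, ] |> dplyr::mutate(psi = 1), isoforms)
  expect_equal(single$psi, 1)

  bad <- dplyr::mutate(isoforms, group = c("functional", NA, "truncated"))
  expect_error(group_psi(psi, bad), class = "cd4atlas_error_annotation")

  set.seed(41)
  p <- runif(3); p <- p / sum(p)
  out2 <- group_psi(dplyr::mutate(psi, psi = p), isoforms)
  expect_equal(sum(out2$psi), 1, tolerance = 1e-9)
})

test_that("the major isoform dominates PSI across the synthetic atlas", {
  at <- small_atlas()
  psi <- estimate_psi(at$sim$compat, at$sim$isoforms)
  by_sub <- psi_by_subtype(psi, at$sim$samples)
  major_psi <- by_sub |>
    dplyr::summarise(top = max(psi), .by = c(subtype, gene_id))
  expect_gt(median(major_psi$top), 0.5)
})
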