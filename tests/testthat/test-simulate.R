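test_that("identical config and seed give bitwise-identical output", {
  cfg <- sim_config(n_genes = 150, su_per_subtype = 4, n_switch_genes = 5,
                    frac_multi_isoform = 0.4, reads_per_gene = 50, seed = 11)
  s1 <- simulate_isoforms(simulate_atlas(cfg))
  s2 <- simulate_isoforms(simulate_atlas(cfg))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$compat, s2$compat)
  expect_identical(s1$truth$planted_psi, s2$truth$planted_psi)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(he_weight = 1.2), "he_weight",
               class = "cd4atlas_error_config")
  expect_error(sim_config(dispersion = -1), "dispersion",
               class = "cd4atlas_error_config")
  expect_error(sim_config(n_genes = 100, su_per_subtype = 40),
               "su_per_subtype", class = "cd4atlas_error_config")
  expect_error(sim_config(n_switch_genes = 10, frac_multi_isoform = 0),
               "n_switch_genes", class = "cd4atlas_error_config")
  expect_error(sim_config(depth_factors = c(1, -1)), "depth_factors",
               class = "cd4atlas_error_config")
})

test_that("without planted effects subtype means agree within Poisson error", {
  cfg <- sim_config(n_genes = 2000, su_per_subtype = 0, su_log2fc = 0,
                    dispersion = 0, depth_factors = rep(1, 12), seed = 3)
  sim <- simulate_atlas(cfg)
  m <- as.matrix(sim$counts[-1])
  groups <- split(seq_len(12), sim$samples$subtype)
  gene_mean <- rowMeans(m)
  keep <- gene_mean > 5
  z <- sapply(groups, function(j) {
    (rowMeans(m[keep, j]) - gene_mean[keep]) / sqrt(gene_mean[keep] / 2)
  })
  # standardized subtype deviations should look standard normal
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.2)
})

test_that("planted SU genes dominate their subtype's normalized means", {
  cfg <- sim_config(seed = 5) # defaults: 2000 genes, 50 SU/subtype, lfc 3
  sim <- simulate_atlas(cfg)
  norm <- normalize_counts(sim$counts, sim$genes, size_factors(sim$counts))
  m <- as.matrix(norm[-1])
  rownames(m) <- norm$gene_id
  groups <- split(seq_len(ncol(m)), sim$samples$subtype)
  hits <- unlist(lapply(names(sim$truth$planted_su), function(st) {
    g <- sim$truth$planted_su[[st]]
    own <- rowMeans(m[g, groups[[st]], drop = FALSE])
    others <- sapply(setdiff(names(groups), st), function(o) {
      rowMeans(m[g, groups[[o]], drop = FALSE])
    })
    own > apply(others, 1, max)
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("planted truth satisfies its structural invariants", {
  at <- small_atlas()
  su <- at$sim$truth$planted_su
  expect_false(anyDuplicated(unlist(su)) > 0)
  sums <- at$sim$truth$planted_psi |>
    dplyr::summarise(s = sum(psi), .by = c(gene_id, subtype))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  cm <- as.matrix(at$sim$counts[-1])
  expect_true(all(cm >= 0 & cm == round(cm)))
})

test_that("read assignment follows PSI x length with binomial noise", {
  cfg <- sim_config(n_genes = 120, su_per_subtype = 0, n_switch_genes = 15,
                    frac_multi_isoform = 0.5, reads_per_gene = 400,
                    ambiguity_rate = 0, depth_factors = rep(1, 12), seed = 9)
  sim <- simulate_isoforms(simulate_atlas(cfg))
  # switch genes have planted PSI (0.8, 0.2); expected read share of the
  # major is 0.8 l1 / (0.8 l1 + 0.2 l2)
  sw <- sim$truth$planted_switches$gene_id[1]
  iso <- sim$isoforms[sim$isoforms$gene_id == sw, ]
  psi <- sim$truth$planted_psi
  psi <- psi[psi$gene_id == sw, ]
  cnt <- sim$compat[grepl(paste0("^", sw, ":"), sim$compat$read_id), ]
  cnt$subtype <- sub("_r[0-9]+$", "", cnt$sample_id)
  for (st in unique(cnt$subtype)) {
    p_st <- psi$psi[psi$subtype == st]
    expected <- p_st[1] * iso$length_bp[1] /
      sum(p_st * iso$length_bp)
    n <- sum(cnt$subtype == st)
    frac <- mean(cnt$isoform_id[cnt$subtype == st] == iso$isoform_id[1])
    expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("planted switch genes flip the estimated major; none flip without planting", {
  cfg <- sim_config(n_genes = 100, su_per_subtype = 0, n_switch_genes = 8,
                    frac_multi_isoform = 0.5, reads_per_gene = 600,
                    ambiguity_rate = 0, depth_factors = rep(1, 12), seed = 13)
  sim <- simulate_isoforms(simulate_atlas(cfg))
  psi <- estimate_psi(sim$compat, sim$isoforms)
  top_by_sample <- psi |>
    dplyr::slice_max(psi, n = 1, by = c(sample_id, gene_id),
                     with_ties = FALSE) |>
    dplyr::mutate(subtype = sub("_r[0-9]+$", "", sample_id))
  sw_pairs <- sim$truth$planted_switches
  expect_gt(nrow(sw_pairs), 0)
  for (i in head(seq_len(nrow(sw_pairs)), 20)) {
    g <- sw_pairs$gene_id[i]
    a_tops <- top_by_sample$isoform_id[top_by_sample$gene_id == g &
                                         top_by_sample$subtype == sw_pairs$subtype_a[i]]
    b_tops <- top_by_sample$isoform_id[top_by_sample$gene_id == g &
                                         top_by_sample$subtype == sw_pairs$subtype_b[i]]
    expect_length(unique(a_tops), 1)
    expect_length(unique(b_tops), 1)
    expect_false(unique(a_tops) == unique(b_tops))
  }

  cfg0 <- sim_config(n_genes = 100, su_per_subtype = 0, n_switch_genes = 0,
                     frac_multi_isoform = 0.5, reads_per_gene = 600,
                     ambiguity_rate = 0, depth_factors = rep(1, 12), seed = 13)
  sim0 <- simulate_isoforms(simulate_atlas(cfg0))
  expect_identical(nrow(sim0$truth$planted_switches), 0L)
  psi0 <- estimate_psi(sim0$compat, sim0$isoforms)
  n_major <- psi0 |>
    dplyr::slice_max(psi, n = 1, by = c(sample_id, gene_id),
                     with_ties = FALSE) |>
    dplyr::distinct(gene_id, isoform_id) |>
    dplyr::count(gene_id)
  expect_true(all(n_major$n == 1))
})

test_that("fixtures round-trip losslessly and degenerate inputs write headers", {
  at <- small_atlas()
  dir <- withr::local_tempdir()
  paths <- write_atlas_fixture(at$sim, dir)
  expect_identical(read_counts(paths[["counts"]]), at$sim$counts)
  expect_identical(read_samples(paths[["samples"]]), at$sim$samples)
  expect_identical(read_genes(paths[["genes"]]), at$sim$genes)
  expect_identical(read_isoforms(paths[["isoforms"]]), at$sim$isoforms)
  expect_identical(read_compat(paths[["compat"]]), at$sim$compat)

  empty <- simulate_isoforms(simulate_atlas(
    sim_config(n_genes = 0, su_per_subtype = 0, n_switch_genes = 0,
               frac_multi_isoform = 0, seed = 1)))
  dir2 <- withr::local_tempdir()
  p2 <- write_atlas_fixture(empty, dir2)
  expect_identical(nrow(read_counts(p2[["counts"]])), 0L)
  expect_identical(names(read_genes(p2[["genes"]])),
                   c("gene_id", "length_bp", "category"))
})

test_that("simulate_isoforms rejects a mismatched configuration", {
  at <- small_atlas()
  other <- sim_config(n_genes = 400, su_per_subtype = 10,
                      frac_multi_isoform = 0.3, n_switch_genes = 10,
                      reads_per_gene = 300, seed = 43)
  expect_error(simulate_isoforms(at$sim, other),
               class = "cd4atlas_error_consistency")
})
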