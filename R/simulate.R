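#' Configuration for the synthetic CD4+ atlas generator
#'
#' Builds and validates the parameter set for [simulate_atlas()] and
#' [simulate_isoforms()]. Defaults emulate the design of the real atlas:
#' six subtypes (Naive, Th1, Th2, Th17, Treg, iTreg) with two biological
#' replicates each, a bimodal log2 expression distribution (a low-expression
#' shoulder and a high-expression peak), planted subtype-upregulated (SU)
#' genes, negative-binomial count noise, multi-isoform genes with a dominant
#' major isoform, and planted major-isoform switches.
#'
#' @param n_subtypes Number of cell subtypes.
#' @param n_replicates Biological replicates per subtype.
#' @param n_genes Number of genes.
#' @param le_mean,le_sd,he_mean,he_sd Means/SDs (log2 normalized expression)
#'   of the low-expression (LE) and high-expression (HE) mixture components.
#' @param he_weight Fraction of genes drawn from the HE component, in (0,1).
#' @param su_per_subtype Planted subtype-upregulated genes per subtype.
#' @param su_log2fc Planted up-regulation effect in log2 units (>= 0).
#' @param dispersion Negative-binomial dispersion alpha >= 0
#'   (variance = mu + alpha * mu^2; 0 gives Poisson counts).
#' @param depth_factors Per-sample library-size multipliers (> 0), length
#'   `n_subtypes * n_replicates`, or `NULL` to draw them log-uniformly in
#'   \[0.7, 1.4\].
#' @param frac_multi_isoform Fraction of genes given 2-4 isoforms.
#' @param n_switch_genes Planted major-isoform switch genes.
#' @param reads_per_gene Mean reads per gene and sample for the
#'   read-isoform compatibility simulation.
#' @param ambiguity_rate Fraction of reads made compatible with a second
#'   isoform of the same gene.
#' @param seed Integer seed; identical configurations give bitwise-identical
#'   output.
#' @param subtypes Optional character vector of subtype names.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, su_per_subtype = 5, seed = 1)
sim_config <- function(n_subtypes = 6, n_replicates = 2, n_genes = 2000,
                       le_mean = 1, le_sd = 1, he_mean = 8, he_sd = 1,
                       he_weight = 0.5,
                       su_per_subtype = 50, su_log2fc = 3,
                       dispersion = 0.05, depth_factors = NULL,
                       frac_multi_isoform = 0.2, n_switch_genes = 30,
                       reads_per_gene = 500, ambiguity_rate = 0.2,
                       seed = 1, subtypes = NULL) {
  cfg <- list(
    n_subtypes = n_subtypes, n_replicates = n_replicates, n_genes = n_genes,
    le_mean = le_mean, le_sd = le_sd, he_mean = he_mean, he_sd = he_sd,
    he_weight = he_weight, su_per_subtype = su_per_subtype,
    su_log2fc = su_log2fc, dispersion = dispersion,
    depth_factors = depth_factors, frac_multi_isoform = frac_multi_isoform,
    n_switch_genes = n_switch_genes, reads_per_gene = reads_per_gene,
    ambiguity_rate = ambiguity_rate, seed = seed, subtypes = subtypes
  )
  bad <- function(field, why) {
    stop_atlas(sprintf("invalid sim_config field '%s': %s", field, why), "config")
  }
  count_fields <- c("n_subtypes", "n_replicates", "n_genes", "su_per_subtype",
                    "n_switch_genes")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      bad(f, "must be a single non-negative integer")
    }
  }
  if (cfg$n_subtypes < 1) bad("n_subtypes", "must be >= 1")
  if (cfg$n_replicates < 1) bad("n_replicates", "must be >= 1")
  for (f in c("le_sd", "he_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) bad(f, "must be > 0")
  }
  if (!is.numeric(cfg$he_weight) || cfg$he_weight <= 0 || cfg$he_weight >= 1) {
    bad("he_weight", "must lie in (0, 1)")
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0) {
    bad("dispersion", "must be >= 0")
  }
  if (!is.numeric(cfg$su_log2fc) || cfg$su_log2fc < 0) {
    bad("su_log2fc", "must be >= 0")
  }
  n_samples <- cfg$n_subtypes * cfg$n_replicates
  if (!is.null(cfg$depth_factors)) {
    if (length(cfg$depth_factors) != n_samples || any(cfg$depth_factors <= 0)) {
      bad("depth_factors", sprintf("must be %d positive values", n_samples))
    }
  }
  if (cfg$su_per_subtype * cfg$n_subtypes > cfg$n_genes) {
    bad("su_per_subtype", "su_per_subtype * n_subtypes exceeds n_genes")
  }
  if (!is.numeric(cfg$frac_multi_isoform) || cfg$frac_multi_isoform < 0 ||
      cfg$frac_multi_isoform > 1) {
    bad("frac_multi_isoform", "must lie in [0, 1]")
  }
  if (cfg$n_switch_genes > cfg$frac_multi_isoform * cfg$n_genes) {
    bad("n_switch_genes", "exceeds frac_multi_isoform * n_genes")
  }
  if (!is.numeric(cfg$ambiguity_rate) || cfg$ambiguity_rate < 0 ||
      cfg$ambiguity_rate > 1) {
    bad("ambiguity_rate", "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$reads_per_gene) || cfg$reads_per_gene < 0) {
    bad("reads_per_gene", "must be >= 0")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != round(cfg$seed) || abs(cfg$seed) >= 2^30) {
    bad("seed", "must be a single integer with |seed| < 2^30")
  }
  if (is.null(cfg$subtypes)) {
    base <- c("Naive", "Th1", "Th2", "Th17", "Treg", "iTreg")
    cfg$subtypes <- if (cfg$n_subtypes <= length(base)) {
      base[seq_len(cfg$n_subtypes)]
    } else {
      c(base, paste0("S", seq_len(cfg$n_subtypes - length(base))))
    }
  }
  if (length(cfg$subtypes) != cfg$n_subtypes || anyDuplicated(cfg$subtypes)) {
    bad("subtypes", "must be n_subtypes unique names")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic CD4+ subtype expression atlas
#'
#' Draws a gene-by-sample count matrix with planted, recoverable structure.
#' Each gene's baseline log2 normalized expression is drawn once from a
#' two-component (LE/HE) Gaussian mixture and shared across subtypes, so
#' non-planted genes are null for differential expression. Per subtype,
#' `su_per_subtype` disjoint subtype-upregulated genes (drawn from the HE
#' component, so that they fall in the expressed classes) receive an extra
#' `su_log2fc` in that subtype only. Counts are drawn from a negative
#' binomial with mean `2^x * depth_factor * length_kb` and dispersion
#' `dispersion` (Poisson when `dispersion = 0`).
#'
#' @param config A [sim_config()].
#' @return A list of class `"atlas_sim"` with elements `counts` (wide
#'   tibble: gene_id + one column per sample), `samples` (sample_id,
#'   subtype, replicate), `genes` (gene_id, length_bp, category), `truth`
#'   (planted ground truth: `planted_su`, `planted_component`, `base_means`,
#'   `depth_factors`) and `config`.
#' @export
#' @examples
#' sim <- simulate_atlas(sim_config(n_genes = 100, su_per_subtype = 3))
#' dim(sim$counts)
simulate_atlas <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_atlas("config must be created by sim_config()", "config")
  }
  set.seed(config$seed)
  n <- config$n_genes
  n_samples <- config$n_subtypes * config$n_replicates
  gene_ids <- if (n > 0) sprintf("G%05d", seq_len(n)) else character(0)

  samples <- tibble::tibble(
    subtype = rep(config$subtypes, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = config$n_subtypes)
  )
  samples <- tibble::tibble(
    sample_id = paste0(samples$subtype, "_r", samples$replicate),
    subtype = samples$subtype, replicate = samples$replicate
  )

  length_bp <- as.integer(round(exp(runif(n, log(500), log(10000)))))
  categories <- c("TF", "cytokine", "receptor", "lncRNA", "other")
  category <- if (n > 0) {
    sample(categories, n, replace = TRUE, prob = c(0.05, 0.03, 0.07, 0.1, 0.75))
  } else {
    character(0)
  }
  genes <- tibble::tibble(gene_id = gene_ids, length_bp = length_bp,
                          category = category)

  component <- if (n > 0) {
    ifelse(runif(n) < config$he_weight, "HE", "LE")
  } else {
    character(0)
  }
  x <- rnorm(n,
             mean = ifelse(component == "HE", config$he_mean, config$le_mean),
             sd = ifelse(component == "HE", config$he_sd, config$le_sd))

  # Plant SU genes on HE-component genes first (signature genes are
  # expressed genes); fall back to LE genes only if the HE pool runs out.
  n_su <- config$su_per_subtype * config$n_subtypes
  he_pool <- which(component == "HE")
  le_pool <- which(component == "LE")
  pool <- c(he_pool[sample.int(length(he_pool))],
            le_pool[sample.int(length(le_pool))])
  if (n_su > length(pool)) {
    stop_atlas("not enough genes to plant SU sets", "config")
  }
  su_idx <- pool[seq_len(n_su)]
  planted_su <- split(
    gene_ids[su_idx],
    rep(config$subtypes, each = config$su_per_subtype)[seq_len(n_su)]
  )
  planted_su <- planted_su[intersect(config$subtypes, names(planted_su))]

  base_means <- matrix(2^x, nrow = n, ncol = config$n_subtypes,
                       dimnames = list(gene_ids, config$subtypes))
  for (st in names(planted_su)) {
    base_means[planted_su[[st]], st] <-
      base_means[planted_su[[st]], st] * 2^config$su_log2fc
  }

  depth <- config$depth_factors
  if (is.null(depth)) depth <- exp(runif(n_samples, log(0.7), log(1.4)))
  names(depth) <- samples$sample_id

  length_kb <- length_bp / 1000
  mu <- sweep(base_means[, samples$subtype, drop = FALSE], 2, depth, `*`)
  mu <- mu * length_kb
  colnames(mu) <- samples$sample_id

  counts <- matrix(0L, nrow = n, ncol = n_samples,
                   dimnames = list(gene_ids, samples$sample_id))
  if (n > 0) {
    draws <- if (config$dispersion == 0) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    counts[] <- as.integer(draws)
  }

  truth <- list(
    planted_su = planted_su,
    planted_component = tidyr::expand_grid(
      gene_id = gene_ids, subtype = config$subtypes
    ) |>
      dplyr::left_join(tibble::tibble(gene_id = gene_ids, component = component),
                       by = "gene_id"),
    base_means = gene_matrix_to_tibble(base_means),
    depth_factors = tibble::tibble(sample_id = samples$sample_id,
                                   depth_factor = unname(depth))
  )

  structure(
    list(counts = gene_matrix_to_tibble(counts), samples = samples,
         genes = genes, truth = truth, config = config),
    class = "atlas_sim"
  )
}

#' Simulate isoform catalog and read-isoform compatibility data
#'
#' Extends an atlas simulation with a multi-isoform catalog, planted
#' per-subtype isoform proportions (PSI), planted major-isoform switches,
#' and simulated read-isoform compatibility triplets. A fraction
#' `frac_multi_isoform` of genes receives 2-4 isoforms; switch genes (two
#' isoforms, PSI 0.8/0.2) have their top isoform swapped in a random
#' non-empty proper subset of subtypes while gene-level counts are
#' untouched. Reads are assigned to isoforms multinomially with probability
#' proportional to PSI times isoform length (longer transcripts yield more
#' reads), and a fraction `ambiguity_rate` of reads is made compatible with
#' exactly one additional isoform of the same gene.
#'
#' @param sim An `"atlas_sim"` from [simulate_atlas()].
#' @param config The same [sim_config()] that produced `sim` (consistency
#'   is checked).
#' @return `sim` augmented with `isoforms` (gene_id, isoform_id, length_bp,
#'   group), `compat` (sample_id, read_id, isoform_id; one row per
#'   compatible pairing) and truth elements `planted_psi` and
#'   `planted_switches`.
#' @export
simulate_isoforms <- function(sim, config = sim$config) {
  if (!inherits(sim, "atlas_sim")) {
    stop_atlas("sim must be produced by simulate_atlas()", "consistency")
  }
  if (!identical(unclass(config), unclass(sim$config))) {
    stop_atlas("config does not match the one stored in the simulation",
               "consistency")
  }
  set.seed(config$seed + 1000003L)
  gene_ids <- sim$genes$gene_id
  n <- length(gene_ids)
  n_multi <- round(config$frac_multi_isoform * n)
  subtypes <- config$subtypes
  s <- length(subtypes)

  if (n_multi == 0) {
    sim$isoforms <- tibble::tibble(gene_id = character(0),
                                   isoform_id = character(0),
                                   length_bp = integer(0), group = character(0))
    sim$compat <- tibble::tibble(sample_id = character(0),
                                 read_id = character(0),
                                 isoform_id = character(0))
    sim$truth$planted_psi <- tibble::tibble(gene_id = character(0),
                                            subtype = character(0),
                                            isoform_id = character(0),
                                            psi = double(0))
    sim$truth$planted_switches <- tibble::tibble(gene_id = character(0),
                                                 subtype_a = character(0),
                                                 subtype_b = character(0))
    return(sim)
  }

  multi_idx <- sort(sample.int(n, n_multi))
  multi_genes <- gene_ids[multi_idx]

  # Switch genes: multi-isoform, HE-component, not planted SU (so they sit
  # in the expressed classes and are not gene-level DE).
  comp <- sim$truth$planted_component
  he_genes <- unique(comp$gene_id[comp$component == "HE"])
  su_genes <- unlist(sim$truth$planted_su, use.names = FALSE)
  switch_pool <- setdiff(intersect(multi_genes, he_genes), su_genes)
  if (config$n_switch_genes > length(switch_pool)) {
    stop_atlas("not enough eligible multi-isoform HE genes to plant switches",
               "config")
  }
  switch_genes <- sort(sample(switch_pool, config$n_switch_genes))

  n_iso <- integer(n_multi)
  names(n_iso) <- multi_genes
  n_iso[] <- sample(2:4, n_multi, replace = TRUE)
  n_iso[switch_genes] <- 2L

  iso_rows <- purrr::map(multi_genes, function(g) {
    k <- n_iso[[g]]
    tibble::tibble(
      gene_id = g,
      isoform_id = paste0(g, ".", seq_len(k)),
      length_bp = as.integer(round(exp(runif(k, log(500), log(10000))))),
      group = c("functional",
                sample(c("functional", "truncated", "non_coding"), k - 1,
                       replace = TRUE))
    )
  })
  isoforms <- dplyr::bind_rows(iso_rows)

  # Planted PSI: one dominant-major vector per gene, shared across
  # subtypes; switch genes get (0.8, 0.2) with the top isoform swapped in a
  # random non-empty proper subset of subtypes.
  psi_rows <- purrr::map(multi_genes, function(g) {
    k <- n_iso[[g]]
    iso <- paste0(g, ".", seq_len(k))
    if (g %in% switch_genes) {
      flips <- rep(FALSE, s)
      while (!any(flips) || all(flips)) flips <- runif(s) < 0.5
      psi <- vapply(seq_len(s), function(i) {
        if (flips[i]) c(0.2, 0.8) else c(0.8, 0.2)
      }, numeric(2))
      tibble::tibble(gene_id = g,
                     subtype = rep(subtypes, each = k),
                     isoform_id = rep(iso, times = s),
                     psi = as.vector(psi))
    } else {
      w <- c(1, runif(k - 1, 0.05, 0.45))
      p <- sort(w / sum(w), decreasing = TRUE)
      tibble::tibble(gene_id = g,
                     subtype = rep(subtypes, each = k),
                     isoform_id = rep(iso, times = s),
                     psi = rep(p, times = s))
    }
  })
  planted_psi <- dplyr::bind_rows(psi_rows)

  planted_major <- planted_psi |>
    dplyr::group_by(.data$gene_id, .data$subtype) |>
    dplyr::slice_max(.data$psi, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pairs <- t(utils::combn(subtypes, 2))
  planted_switches <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ma <- planted_major[planted_major$subtype == a, ]
    mb <- planted_major[planted_major$subtype == b, ]
    j <- dplyr::inner_join(ma, mb, by = "gene_id", suffix = c("_a", "_b"))
    j <- j[j$isoform_id_a != j$isoform_id_b, ]
    tibble::tibble(gene_id = j$gene_id, subtype_a = a, subtype_b = b)
  }) |> dplyr::bind_rows()

  # Read-isoform compatibility triplets, per multi-isoform gene and sample.
  depth <- sim$truth$depth_factors$depth_factor
  names(depth) <- sim$truth$depth_factors$sample_id
  sample_ids <- sim$samples$sample_id
  sample_subtype <- setNames(sim$samples$subtype, sample_ids)

  compat_rows <- purrr::map(multi_genes, function(g) {
    k <- n_iso[[g]]
    iso <- paste0(g, ".", seq_len(k))
    len <- isoforms$length_bp[match(iso, isoforms$isoform_id)]
    psi_g <- planted_psi[planted_psi$gene_id == g, ]
    purrr::map(sample_ids, function(sid) {
      p <- psi_g$psi[psi_g$subtype == sample_subtype[[sid]]][seq_len(k)]
      n_reads <- rpois(1, config$reads_per_gene * depth[[sid]])
      if (n_reads == 0) return(NULL)
      prob <- p * len
      origin <- sample.int(k, n_reads, replace = TRUE, prob = prob / sum(prob))
      read_id <- paste0(g, ":", sid, ":", seq_len(n_reads))
      amb <- runif(n_reads) < config$ambiguity_rate
      extra <- integer(0)
      if (any(amb)) {
        off <- 1L + floor(runif(sum(amb)) * (k - 1))
        extra <- 1L + (origin[amb] - 1L + off) %% k
      }
      tibble::tibble(
        sample_id = sid,
        read_id = c(read_id, read_id[amb]),
        isoform_id = iso[c(origin, extra)]
      )
    }) |> dplyr::bind_rows()
  })
  compat <- dplyr::bind_rows(compat_rows)

  sim$isoforms <- isoforms
  sim$compat <- compat
  sim$truth$planted_psi <- planted_psi
  sim$truth$planted_switches <- planted_switches
  sim
}
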