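# Independent brute-force oracles and small shared fixtures.

# Median-of-ratios size factors, written naively and independently of the
# package implementation: per-gene geometric mean over samples, per-sample
# median of count/reference over genes positive everywhere.
bf_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  ref <- apply(m[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j) {
    median(m[keep, j] / ref)
  }, 0)
}

# Benjamini-Hochberg step-up, literal definition: sort ascending,
# q_(i) = min_{k >= i} p_(k) * m / k, cap at 1, restore input order.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# Small default atlas reused across tests (cached per session).
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 400, su_per_subtype = 10,
                        frac_multi_isoform = 0.3, n_switch_genes = 10,
                        reads_per_gene = 300, seed = 42)
      sim <- simulate_isoforms(simulate_atlas(cfg))
      sf <- size_factors(sim$counts)
      cache <<- list(
        sim = sim, sf = sf,
        norm = normalize_counts(sim$counts, sim$genes, sf)
      )
    }
    cache
  }
})

# Wide tibble from a plain matrix with default ids.
wide_counts <- function(m, gene_ids = NULL, sample_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(gene_ids, sample_ids)
  storage.mode(m) <- "integer"
  tibble::as_tibble(m, rownames = "gene_id")
}
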