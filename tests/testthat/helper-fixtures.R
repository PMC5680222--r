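# Shared fixtures built in code.

# a small cohort spec that keeps unit tests fast; planted structure is the
# same as the default, only smaller
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_samples = 120L, n_cpgs = 300L, n_genes = 150L,
              cluster2 = list(n_cpgs_A = 20L, n_cpgs_B = 20L,
                              n_genes_A = 12L, n_genes_B = 8L,
                              beta_low = 0.1, beta_high = 0.8,
                              expr_effect = 1),
              cluster1 = list(n_cpgs_A = 20L, n_cpgs_B = 20L, n_genes = 15L,
                              immune_beta_low = 0.1, immune_beta_high = 0.8,
                              expr_effect = 3),
              genome = list(n_chroms = 2L, chrom_length = 3e6),
              seed = seed, ...)
}

# brute-force per-pair correlation screen used as the oracle for the chunked
# engine: plain loops over rows, stats::cor.test as the reference test
oracle_emqtl <- function(meth, expr, alpha = 0.05) {
  shared <- sort(intersect(colnames(meth), colnames(expr)))
  meth <- meth[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  usable <- function(m) {
    apply(m, 1L, function(x) {
      x <- x[!is.na(x)]
      length(x) >= 3L && var(x) > 0
    })
  }
  meth <- meth[usable(meth), , drop = FALSE]
  expr <- expr[usable(expr), , drop = FALSE]
  m <- nrow(meth) * nrow(expr)
  out <- list()
  for (i in seq_len(nrow(meth))) for (j in seq_len(nrow(expr))) {
    x <- meth[i, ]; y <- expr[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || var(x[ok]) == 0 || var(y[ok]) == 0) next
    ct <- suppressWarnings(cor.test(x[ok], y[ok]))
    if (ct$p.value * m < alpha) {
      out[[length(out) + 1L]] <- data.frame(
        cpg = rownames(meth)[i], gene = rownames(expr)[j],
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  list(m = m, pairs = do.call(rbind, c(out, make.row.names = FALSE)))
}

# exact hypergeometric upper tail by combinatorial summation
oracle_hyper_p <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# quadratic interval-overlap scan
oracle_overlap <- function(track, chrom, start, end) {
  which(track$chrom == chrom & track$start < end & track$end > start)
}

random_track <- function(n, chroms = c("chr1", "chr2"), len = 1e5) {
  start <- sample.int(len, n, replace = TRUE)
  data.table::data.table(chrom = sample(chroms, n, replace = TRUE),
                         start = start,
                         end = start + sample.int(500, n, replace = TRUE),
                         label = paste0("iv", seq_len(n)))
}
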