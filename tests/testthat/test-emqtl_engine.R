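test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10, 10), 5e-4)
  # overflow-safe for > 1e10 tests
  expect_gt(bonferroni_threshold(0.05, 2e5, 2e5), 0)
  expect_equal(signif(bonferroni_threshold(0.05, 189026, 17558), 3), 1.51e-11)
})

test_that("iqr_filter keeps strictly-above-threshold rows with interpolated quartiles", {
  m <- rbind(const = rep(0.5, 6),
             alt = rep(c(0, 1), 3),
             ramp = c(0.1, 0.2, 0.3, 0.4, 0.5, NA),
             sparse = c(0.1, 0.9, NA, NA, NA, NA))
  colnames(m) <- paste0("s", 1:6)
  out <- iqr_filter(m, min_iqr = 0.1)
  expect_setequal(out$retained, c("alt", "ramp"))
  # hand quantile computation (type-7 linear interpolation) for the ramp row
  expect_equal(unname(quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.75, type = 7) -
                 quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.25, type = 7)), 0.2)
  expect_equal(out$dropped$reason[out$dropped$cpg == "const"], "low_iqr")
  expect_equal(out$dropped$reason[out$dropped$cpg == "sparse"],
               "too_few_values")
  # boundary is strict: IQR exactly equal to the threshold is removed
  m2 <- rbind(edge = c(0.4, 0.4, 0.5, 0.5))
  colnames(m2) <- paste0("s", 1:4)
  expect_length(iqr_filter(m2, min_iqr = 0.1)$retained, 0L)
})

test_that("impute_knn drops high-missingness rows and averages the k nearest rows", {
  m <- rbind(a = c(1, 2, 3, 4),
             b = c(1.1, 2.1, 3.1, 4.1),
             c = c(0.9, 1.9, 2.9, 3.9),
             d = c(10, 11, 12, 13),
             e = c(1, 2, NA, 4),
             f = c(NA, NA, NA, 1))
  colnames(m) <- paste0("s", 1:4)
  out <- impute_knn(m, k = 2, max_missing_fraction = 0.5)
  expect_equal(out$removed, "f")
  # nearest two rows to e are a and b or c (hand check: a dist 0, b ~0.1, c ~0.1)
  d2 <- sapply(c("a", "b", "c", "d"), function(r) {
    sh <- !is.na(m["e", ]) & !is.na(m[r, ])
    sqrt(sum((m["e", sh] - m[r, sh])^2) / sum(sh) * ncol(m))
  })
  nb <- names(sort(d2))[1:2]
  expect_equal(out$matrix["e", "s3"], mean(m[nb, "s3"]))
  # no-missing matrix returned unchanged
  expect_identical(impute_knn(m[1:4, ], k = 2)$matrix, m[1:4, ])
})

test_that("pearson_with_p matches the t-distribution test and flags untestable input", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 6)
  got <- pearson_with_p(x, y)
  # direct covariance computation
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(round(got$r, 4), 0.9864)
  expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  expect_equal(pearson_with_p(1:10, 10:1)$p, 0)   # |r| = 1
  expect_equal(pearson_with_p(1:10, 1:10)$p, 0)
  set.seed(1)
  z <- rnorm(20)
  expect_equal(pearson_with_p(z, rep(c(1, -1), 10) * 0 + z * 0 + 1)$reason,
               "zero_variance")
  expect_equal(pearson_with_p(c(1, NA, 3), c(NA, 2, 3))$reason,
               "insufficient_n")
  # r = 0 gives p = 1
  expect_equal(pearson_with_p(c(1, 2, 1, 2), c(3, 3, 4, 4))$p, 1)
})

test_that("chunked all-pair screen equals the per-pair oracle for any chunk size", {
  set.seed(11)
  meth <- matrix(runif(50 * 30), 50, 30,
                 dimnames = list(sprintf("cg%02d", 1:50), sprintf("s%02d", 1:30)))
  expr <- matrix(rnorm(40 * 30), 40, 30,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:30)))
  # plant a few strong associations and some missing values
  expr[1, ] <- -3 * meth[1, ] + rnorm(30, sd = 0.1)
  expr[2, ] <- 2 * meth[2, ] + rnorm(30, sd = 0.1)
  meth[3, 1:4] <- NA; expr[5, 2:3] <- NA
  want <- oracle_emqtl(meth, expr, alpha = 0.5)
  key <- function(d) paste(d$cpg, d$gene)
  for (cs in c(1L, 7L, 64L, 1000L)) {
    got <- all_pair_emqtl(meth, expr, alpha = 0.5, chunk_size = cs)
    expect_equal(got$m, want$m)
    expect_setequal(key(got$pairs), key(want$pairs))
    ord <- match(key(want$pairs), key(got$pairs))
    expect_equal(got$pairs$r[ord], want$pairs$r, tolerance = 1e-10)
    expect_equal(got$pairs$p[ord], want$pairs$p, tolerance = 1e-10)
  }
  expect_error(all_pair_emqtl(meth, expr, chunk_size = 0), "chunk_size")
})

test_that("screen results are invariant to joint sample permutation and alpha = 0 empties them", {
  set.seed(12)
  meth <- matrix(runif(10 * 20), 10, 20,
                 dimnames = list(paste0("cg", 1:10), paste0("s", 1:20)))
  expr <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  a <- all_pair_emqtl(meth, expr, alpha = 0.5, keep_all = TRUE)
  perm <- sample(20)
  b <- all_pair_emqtl(meth[, perm], expr[, perm], alpha = 0.5, keep_all = TRUE)
  expect_equal(a$pairs, b$pairs, tolerance = 1e-12)
  expect_equal(nrow(all_pair_emqtl(meth, expr, alpha = 0)$pairs), 0L)
  # a zero-noise planted pair is retained with p_bonf = 0
  expr2 <- expr; expr2[1, ] <- meth[1, ]
  res <- all_pair_emqtl(meth, expr2, alpha = 0.05)
  hit <- res$pairs[res$pairs$cpg == "cg1" & res$pairs$gene == "g1", ]
  expect_equal(hit$p_bonf, 0)
})

test_that("validation re-tests pairs with the testable-pair correction and tracks untestables", {
  co <- generate_cohort(small_spec(seed = 4L))
  halves <- split_cohort(co, 0.5, seed = 9L, probe_drop_fraction = 0.1)
  keep <- iqr_filter(halves$discovery$meth)
  disc <- all_pair_emqtl(halves$discovery$meth[keep$retained, , drop = FALSE],
                         halves$discovery$expr)
  vali <- validate_pairs(disc, halves$validation$meth, halves$validation$expr)
  s <- vali$summary
  expect_equal(s$n_testable, s$n_input - s$n_untestable)
  expect_equal(s$n_input, nrow(disc$pairs))
  expect_equal(s$validation_rate, s$n_validated / s$n_testable)
  expect_equal(vali$m, s$n_testable)
  # dropped probes surface as missing_probe untestables
  dropped_in_disc <- intersect(halves$dropped$cpgs, disc$pairs$cpg)
  if (length(dropped_in_disc)) {
    expect_true(all(vali$untestable$reason[
      vali$untestable$cpg %in% dropped_in_disc] == "missing_probe"))
  }
  # every validated pair keeps its discovery sign by default
  key <- paste(vali$pairs$cpg, vali$pairs$gene)
  dkey <- paste(disc$pairs$cpg, disc$pairs$gene)
  expect_true(all(vali$pairs$sign == disc$pairs$sign[match(key, dkey)]))
  # planted-clique pairs validate at a high rate in a 50/50 split
  same_cluster <- outer(co$truth_cpgs$cluster, co$truth_genes$cluster, "==")
  truth_key <- paste(co$truth_cpgs$cpg[row(same_cluster)[same_cluster]],
                     co$truth_genes$gene[col(same_cluster)[same_cluster]])
  ukey <- paste(vali$untestable$cpg, vali$untestable$gene)
  planted_testable <- setdiff(intersect(dkey, truth_key), ukey)
  expect_gt(length(planted_testable), 100L)
  planted_rate <- mean(planted_testable %in% key)
  expect_gte(planted_rate, 0.85)
})

test_that("rediscovery_rate counts shared (cpg, gene) keys", {
  mk <- function(cpg, gene) {
    structure(list(pairs = data.table::data.table(
      cpg = cpg, gene = gene, r = 0.5, n = 10L, p = 1e-9, p_bonf = 1e-4,
      sign = "positive")), class = "emqtl_result")
  }
  a <- mk(c("c1", "c2", "c3", "c4"), c("g1", "g2", "g3", "g4"))
  b <- mk(c("c1", "c2", "c4"), c("g1", "g2", "g4"))
  expect_equal(rediscovery_rate(a, a), 1)
  expect_equal(rediscovery_rate(a, b), 0.75)
  expect_equal(rediscovery_rate(b, mk("cX", "gX")), 0)
  expect_error(rediscovery_rate(mk(character(0), character(0)), a), "empty")
})

test_that("pair tables round-trip through gzip TSV serialization", {
  co <- generate_cohort(small_spec(seed = 2L))
  keep <- iqr_filter(co$meth)
  res <- all_pair_emqtl(co$meth[keep$retained, , drop = FALSE], co$expr)
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_emqtl_pairs(res, f)
  back <- read_emqtl_pairs(f)
  expect_equal(back$stage, "discovery")
  expect_equal(as.data.frame(back$pairs), as.data.frame(res$pairs),
               tolerance = 1e-12)
})
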