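test_that("hypergeometric enrichment matches exact combinatorial summation", {
  # the worked 20/10/5 example: P(all 5 draws annotated) = C(10,5)/C(20,5)
  r <- hypergeom_enrichment(paste0("q", 1:5), paste0("q", 1:10),
                            paste0("q", 1:20))
  expect_equal(r$p, 252 / 15504, tolerance = 1e-12)
  expect_equal(r$ratio, (5 / 5) / (10 / 20))

  # sweep of instances with N <= 60 against the summation oracle
  set.seed(41)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    bg <- paste0("id", seq_len(N))
    ann <- sample(bg, K)
    q <- sample(bg, n)
    k <- length(intersect(q, ann))
    got <- hypergeom_enrichment(q, ann, bg)
    expect_equal(got$p, oracle_hyper_p(N, K, n, k), tolerance = 1e-12)
    expect_equal(got$n_query_hits, k)
  }

  # query equal to the annotated set gives ratio N/K; empty annotation is null
  bg <- paste0("b", 1:30)
  r2 <- hypergeom_enrichment(bg[1:6], bg[1:6], bg)
  expect_equal(r2$ratio, 30 / 6)
  r3 <- hypergeom_enrichment(bg[1:6], character(0), bg)
  expect_equal(r3$ratio, 0); expect_equal(r3$p, 1)
  expect_error(hypergeom_enrichment("x", bg[1], bg), "subset")
})

test_that("chromatin-state profiles collapse states conservatively", {
  seg <- data.table::data.table(
    chrom = "chr1",
    start = c(0L, 100L, 200L, 300L, 400L),
    end = c(100L, 200L, 300L, 400L, 500L),
    label = c("Enhancer", "Enhancer+CTCF", "Promoter", "Poised Promoter",
              "Heterochromatin"))
  cpg_map <- data.table::data.table(
    cpg = paste0("c", 1:10),
    chrom = "chr1", pos = c(10L, 150L, 250L, 350L, 450L, 20L, 30L, 460L,
                            470L, 600L))
  bg <- cpg_map$cpg
  prof_on <- chromhmm_profile(c("c1", "c2"), cpg_map, seg, bg, collapse = TRUE)
  prof_off <- chromhmm_profile(c("c1", "c2"), cpg_map, seg, bg,
                               collapse = FALSE)
  # collapsed hits equal the sum of constituent-state hits
  enh_on <- prof_on[prof_on$category == "Enhancer", ]
  expect_equal(enh_on$n_query_hits, 2L)
  expect_equal(enh_on$n_background_hits,
               sum(prof_off$n_background_hits[
                 prof_off$category %in% c("Enhancer", "Enhancer+CTCF")]))
  expect_equal(sum(prof_off$n_background_hits[
    prof_off$category %in% c("Promoter", "Poised Promoter")]),
    prof_on[prof_on$category == "Promoter", ]$n_background_hits)
  # a CpG outside all segments lands in the sentinel state
  expect_true("unannotated" %in% prof_on$category)

  # a random query from the background should not be enriched too often
  set.seed(42)
  co <- generate_cohort(small_spec(seed = 12L))
  ann <- generate_annotations(co, seed = 5L)
  hits <- vapply(1:40, function(i) {
    q <- sample(co$cpg_map$cpg, 30)
    pr <- chromhmm_profile(q, co$cpg_map, ann$segmentation, co$cpg_map$cpg)
    min(pr$p)
  }, numeric(1L))
  expect_lte(mean(hits < 0.05 / 7), 0.2)  # loose null sanity bound
})

test_that("peak windows follow the +/- 200 bp rule", {
  track <- data.table::data.table(chrom = "chr1", start = 1000L, end = 1200L,
                                  label = "pk")
  cpg_map <- data.table::data.table(cpg = c("in", "near", "far"),
                                    chrom = "chr1",
                                    pos = c(1100L, 1350L, 1500L))
  bg <- cpg_map$cpg
  r0 <- peak_enrichment(c("in", "near"), cpg_map, track, bg, half_width = 0)
  expect_equal(r0$n_query_hits, 1L)      # only the in-peak base
  r200 <- peak_enrichment(c("in", "near"), cpg_map, track, bg,
                          half_width = 200)
  expect_equal(r200$n_query_hits, 2L)    # 150 bp from the edge now hits
  r_far <- peak_enrichment("far", cpg_map, track, bg, half_width = 200)
  expect_equal(r_far$n_query_hits, 0L)   # 300 bp away stays out
})

test_that("permutation enrichment has the add-one floor, seed stability and hypergeometric limit", {
  co <- generate_cohort(small_spec(seed = 13L))
  ann <- generate_annotations(co, seed = 3L)
  tf <- ann$peaks[c("ERA", "FOXA1", "GATA3")]
  c2a <- co$truth_cpgs$cpg[co$truth_cpgs$cluster == "cluster2" &
                             co$truth_cpgs$sub == "A"]
  perm <- permutation_enrichment(c2a, co$cpg_map, tf, co$cpg_map$cpg,
                                 n_perm = 1000L, seed = 17L)
  expect_equal(perm$p, 1 / 1001)  # observed beats every permutation
  perm2 <- permutation_enrichment(c2a, co$cpg_map, tf, co$cpg_map$cpg,
                                  n_perm = 1000L, seed = 17L)
  expect_identical(perm$perm_counts, perm2$perm_counts)
  expect_error(permutation_enrichment(c2a, co$cpg_map, tf, co$cpg_map$cpg,
                                      n_perm = 0L), "n_perm")

  # permutation p converges to the hypergeometric p on a non-degenerate query
  set.seed(7)
  q <- sample(co$cpg_map$cpg, 150)
  hyp <- peak_enrichment(q, co$cpg_map, tf, co$cpg_map$cpg)
  pm <- permutation_enrichment(q, co$cpg_map, tf, co$cpg_map$cpg,
                               n_perm = 20000L, seed = 23L)
  se <- sqrt(hyp$p * (1 - hyp$p) / 20000)
  expect_lte(abs(pm$p - hyp$p), 2 * se + 1 / 20001)
})

test_that("loop support requires opposite anchors and is orientation-symmetric", {
  loops <- data.table::data.table(
    loop_id = c("l1", "l2"),
    chromA = "chr1", startA = c(100L, 5000L), endA = c(200L, 5100L),
    chromB = c("chr1", "chr1"), startB = c(1000L, 6000L),
    endB = c(1100L, 6100L))
  cpg_map <- data.table::data.table(cpg = c("cA", "cB", "cSame"),
                                    chrom = "chr1",
                                    pos = c(150L, 1050L, 120L))
  gene_models <- data.table::data.table(
    gene = c("gB", "gSame", "gNo"), chrom = "chr1",
    tss = c(1050L, 150L, 9000L), strand = "+")
  pairs <- data.table::data.table(cpg = c("cA", "cSame", "cA"),
                                  gene = c("gB", "gSame", "gNo"))
  hit <- emqtl:::loop_supported(pairs, loops, cpg_map, gene_models)
  expect_identical(hit, c(TRUE, FALSE, FALSE))  # same-anchor pair is a miss
  # swap all anchors: nothing changes
  swapped <- data.table::data.table(
    loop_id = loops$loop_id, chromA = loops$chromB, startA = loops$startB,
    endA = loops$endB, chromB = loops$chromA, startB = loops$startA,
    endB = loops$endA)
  expect_identical(emqtl:::loop_supported(pairs, swapped, cpg_map,
                                          gene_models), hit)
  # worked ratio example: background 10 pairs with 2 supported, query of 5
  # holding both
  bg_pairs <- data.table::data.table(
    cpg = c("cA", "cB", rep("cSame", 8)),
    gene = c("gB", "gB", paste0("gNo", 1:8)))
  gm2 <- rbind(gene_models,
               data.table::data.table(gene = paste0("gNo", 1:8),
                                      chrom = "chr1", tss = 9000L,
                                      strand = "+"))
  cpgm2 <- cpg_map
  q <- bg_pairs[c(1, 2, 3, 4, 5), ]
  le <- loop_enrichment(q, loops, cpgm2, gm2, bg_pairs)
  expect_equal(le$ratio, (2 / 5) / (2 / 10))
})

test_that("local pairing uses the 10 kb same-chromosome rule", {
  cpg_map <- data.table::data.table(cpg = c("c1", "c2", "c3"),
                                    chrom = c("chr1", "chr1", "chr2"),
                                    pos = c(5000L, 40000L, 5000L))
  gene_models <- data.table::data.table(gene = c("g1", "g2"),
                                        chrom = "chr1",
                                        tss = c(14999L, 15001L),
                                        strand = "+")
  pairs <- data.table::data.table(cpg = c("c1", "c1", "c2", "c3"),
                                  gene = c("g1", "g2", "g1", "g1"))
  lp <- local_pairs(pairs, cpg_map, gene_models)
  expect_identical(lp$pairs$local, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lp$pairs$distance[1:3], c(9999, 10001, 25001))
  expect_true(is.na(lp$pairs$distance[4]))        # cross-chromosome
  expect_equal(lp$local_gene_fraction, 0.5)       # g1 local, g2 not
})

test_that("gene-set enrichment ranks the planted set first", {
  co <- generate_cohort(small_spec(seed = 14L))
  g1 <- co$truth_genes$gene[co$truth_genes$cluster == "cluster1"]
  bg <- rownames(co$expr)
  set.seed(8)
  collection <- list(IMMUNE_SET = g1,
                     RANDOM_A = sample(bg, 40),
                     RANDOM_B = sample(bg, 25))
  res <- gene_set_enrichment(g1, collection, bg)
  expect_equal(res$category[1], "IMMUNE_SET")
  expect_lt(res$p[1], 1e-6)
  # disjoint query has all-zero ratios
  res0 <- gene_set_enrichment(setdiff(bg, unlist(collection))[1:10],
                              collection, bg)
  expect_true(all(res0$ratio == 0))
  expect_error(gene_set_enrichment(g1, collection, "not_a_gene"), "shares no")
})

test_that("target overlap reports per-list and union fractions", {
  lists <- list(ER = c("a", "b"), FOXA1 = c("b", "c"), GATA3 = c("d"))
  out <- target_overlap(c("a", "b", "x"), lists)
  expect_equal(unname(out$per_list), c(2 / 3, 1 / 3, 0))
  expect_equal(out$union_fraction, 2 / 3)
  expect_equal(target_overlap(c("a", "c"), lists)$union_fraction, 1)
  expect_equal(target_overlap(c("x", "y"), lists)$union_fraction, 0)
})

test_that("median-difference screening needs both the 0.1 gap and a low rank-sum p", {
  set.seed(51)
  a <- paste0("a", 1:15); b <- paste0("b", 1:15)
  meth <- rbind(
    clear = c(rnorm(15, 0.20, 0.02), rnorm(15, 0.50, 0.02)),
    small_gap = c(rnorm(15, 0.20, 0.01), rnorm(15, 0.25, 0.01)),
    same = rep(0.4, 30))
  colnames(meth) <- c(a, b)
  out <- differential_median_cpgs(meth, a, b)
  expect_true(out$pass[out$cpg == "clear"])
  expect_false(out$pass[out$cpg == "small_gap"])   # gap rule fails despite p
  expect_lt(out$p[out$cpg == "small_gap"], 0.05)
  expect_false(out$pass[out$cpg == "same"])
  expect_gt(out$p[out$cpg == "same"], 0.5)
})
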