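# Synthetic breast-cancer-like cohorts with planted emQTL structure:
#   Cluster 2 - an ER-lineage clique: CpGs hypomethylated in ER+ tumors (2A)
#     or ER- tumors (2B), anti-correlated with TF-target genes.
#   Cluster 1 - an infiltration clique: CpG methylation and immune-gene
#     expression driven by the per-sample lymphocyte infiltration fraction
#     through a two-component tissue mixture.

# Run code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic emQTL cohort
#'
#' Collects every knob of the generator with defaults that emulate a
#' two-clique tumor cohort: an ER-lineage bicluster of enhancer CpGs
#' anti-correlated with TF-target genes (with an oppositely methylated
#' sub-cluster) and an immune-infiltration bicluster arising from a
#' cancer/lymphocyte tissue mixture.
#'
#' @param n_samples,n_cpgs,n_genes Cohort dimensions.
#' @param er_positive_fraction Probability a sample is ER positive. The
#'   default 0.6 keeps both quartiles of a lineage-switched CpG strictly
#'   inside the majority methylation mode, so planted CpGs robustly pass an
#'   interquartile-range variability filter; fractions near 0.75 put the
#'   upper quartile on the group boundary, where the IQR of a bimodal CpG
#'   degenerates.
#' @param cluster2 ER-lineage clique: counts of A/B CpGs and genes, the two
#'   methylation levels `beta_low`/`beta_high` switched by ER status, and the
#'   expression shift `expr_effect` of target genes in their favoured group.
#' @param cluster1 Infiltration clique: counts of A/B CpGs, number of immune
#'   genes, the pure-tissue methylation levels mixed by the infiltration
#'   fraction, and the per-unit-infiltration expression slope `expr_effect`.
#' @param infiltration_beta Shape parameters (a, b) of the Beta law for the
#'   per-sample lymphocyte infiltration fraction.
#' @param noise_sd_meth Methylation noise SD on the logit scale.
#' @param noise_sd_expr Expression noise SD (additive, linear scale).
#' @param genome Number of chromosomes and common chromosome length (bp).
#' @param local_pair_fraction Fraction of Cluster-2 genes given a clique CpG
#'   within 10 kb of their TSS (cis pairing); remaining clique CpGs are kept
#'   out of all Cluster-2 TSS windows so the planted fraction is exact.
#' @param seed Integer seed; the same spec always generates the same cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200L,
                        n_cpgs = 2000L,
                        n_genes = 1000L,
                        er_positive_fraction = 0.6,
                        cluster2 = list(n_cpgs_A = 100L, n_cpgs_B = 100L,
                                        n_genes_A = 50L, n_genes_B = 30L,
                                        beta_low = 0.1, beta_high = 0.8,
                                        expr_effect = 1),
                        cluster1 = list(n_cpgs_A = 100L, n_cpgs_B = 100L,
                                        n_genes = 60L,
                                        immune_beta_low = 0.1,
                                        immune_beta_high = 0.8,
                                        expr_effect = 3),
                        infiltration_beta = c(a = 1.5, b = 3.5),
                        noise_sd_meth = 0.3,
                        noise_sd_expr = 0.5,
                        genome = list(n_chroms = 2L, chrom_length = 1e7),
                        local_pair_fraction = 0.32,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
               n_genes = as.integer(n_genes),
               er_positive_fraction = er_positive_fraction,
               cluster2 = cluster2, cluster1 = cluster1,
               infiltration_beta = infiltration_beta,
               noise_sd_meth = noise_sd_meth, noise_sd_expr = noise_sd_expr,
               genome = genome, local_pair_fraction = local_pair_fraction,
               seed = as.integer(seed))
  n_planted_cpgs <- cluster1$n_cpgs_A + cluster1$n_cpgs_B +
    cluster2$n_cpgs_A + cluster2$n_cpgs_B
  n_planted_genes <- cluster1$n_genes + cluster2$n_genes_A + cluster2$n_genes_B
  if (n_planted_cpgs > n_cpgs) stop("planted CpG counts exceed n_cpgs")
  if (n_planted_genes > n_genes) stop("planted gene counts exceed n_genes")
  if (!(cluster2$beta_low >= 0 && cluster2$beta_low < cluster2$beta_high &&
          cluster2$beta_high <= 1))
    stop("need 0 <= beta_low < beta_high <= 1")
  if (!(cluster1$immune_beta_low >= 0 &&
          cluster1$immune_beta_low < cluster1$immune_beta_high &&
          cluster1$immune_beta_high <= 1))
    stop("need 0 <= immune_beta_low < immune_beta_high <= 1")
  if (er_positive_fraction <= 0 || er_positive_fraction >= 1)
    stop("er_positive_fraction must be in (0,1)")
  if (noise_sd_meth < 0 || noise_sd_expr < 0) stop("noise sds must be >= 0")
  if (local_pair_fraction < 0 || local_pair_fraction > 1)
    stop("local_pair_fraction must be in [0,1]")
  structure(spec, class = "cohort_spec")
}

logit <- function(p) qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

# Add logit-scale gaussian noise to a beta-value matrix; sd = 0 returns the
# input untouched so zero-noise cohorts are exact.
beta_noise <- function(mu, sd) {
  if (sd == 0) return(mu)
  plogis(logit(mu) + matrix(rnorm(length(mu), sd = sd), nrow(mu), ncol(mu)))
}

#' Generate a synthetic cohort with planted emQTL cliques
#'
#' Draws ER status and infiltration fraction per sample, then builds the
#' methylation and expression matrices around them. Cluster-2A CpGs sit at
#' `beta_low` in ER+ and `beta_high` in ER- samples (2B reversed); Cluster-2A
#' genes are shifted up by `expr_effect` in ER+ samples (2B reversed).
#' Cluster-1A CpG methylation is the tissue mixture
#' `(1 - f) * beta_high + f * immune_beta_low` of cancer and lymphocyte
#' methylation at infiltration fraction `f` (1B reversed), and Cluster-1
#' (immune) gene expression increases linearly with `f`. Background CpGs are
#' logit-normal around fixed means; background genes are gaussian.
#' Methylation noise is applied on the logit scale so beta values stay in
#' \[0,1\].
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `meth`, `expr`,
#'   `samples`, `cpg_map`, `gene_models`, `truth_cpgs`, `truth_genes`,
#'   `standard_genes` (the planted immune genes) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_samples
    samples <- sprintf("S%03d", seq_len(ns))
    er <- ifelse(rbinom(ns, 1L, spec$er_positive_fraction) == 1L,
                 "ER+", "ER-")
    f <- rbeta(ns, spec$infiltration_beta[[1L]], spec$infiltration_beta[[2L]])

    c1 <- spec$cluster1; c2 <- spec$cluster2
    cpgs <- sprintf("cg%07d", seq_len(spec$n_cpgs))
    genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
    idx <- function(n, from) seq.int(from, length.out = n)
    i1A <- idx(c1$n_cpgs_A, 1L)
    i1B <- idx(c1$n_cpgs_B, c1$n_cpgs_A + 1L)
    i2A <- idx(c2$n_cpgs_A, c1$n_cpgs_A + c1$n_cpgs_B + 1L)
    i2B <- idx(c2$n_cpgs_B, c1$n_cpgs_A + c1$n_cpgs_B + c2$n_cpgs_A + 1L)
    g1 <- idx(c1$n_genes, 1L)
    g2A <- idx(c2$n_genes_A, c1$n_genes + 1L)
    g2B <- idx(c2$n_genes_B, c1$n_genes + c2$n_genes_A + 1L)

    erp <- er == "ER+"
    mu <- matrix(NA_real_, spec$n_cpgs, ns, dimnames = list(cpgs, samples))
    mu[i2A, ] <- matrix(ifelse(erp, c2$beta_low, c2$beta_high),
                        length(i2A), ns, byrow = TRUE)
    mu[i2B, ] <- matrix(ifelse(erp, c2$beta_high, c2$beta_low),
                        length(i2B), ns, byrow = TRUE)
    mix_a <- (1 - f) * c1$immune_beta_high + f * c1$immune_beta_low
    mix_b <- (1 - f) * c1$immune_beta_low + f * c1$immune_beta_high
    mu[i1A, ] <- matrix(mix_a, length(i1A), ns, byrow = TRUE)
    mu[i1B, ] <- matrix(mix_b, length(i1B), ns, byrow = TRUE)
    bg_cpg <- setdiff(seq_len(spec$n_cpgs),
                      c(i1A, i1B, i2A, i2B))
    mu[bg_cpg, ] <- matrix(runif(length(bg_cpg), 0.05, 0.95), length(bg_cpg),
                           ns)
    meth <- beta_noise(mu, spec$noise_sd_meth)

    ex <- matrix(NA_real_, spec$n_genes, ns, dimnames = list(genes, samples))
    ex[g2A, ] <- matrix(c2$expr_effect * erp, length(g2A), ns, byrow = TRUE)
    ex[g2B, ] <- matrix(c2$expr_effect * !erp, length(g2B), ns, byrow = TRUE)
    ex[g1, ] <- matrix(c1$expr_effect * f, length(g1), ns, byrow = TRUE)
    bg_gene <- setdiff(seq_len(spec$n_genes), c(g1, g2A, g2B))
    ex[bg_gene, ] <- matrix(rnorm(length(bg_gene)), length(bg_gene), ns)
    if (spec$noise_sd_expr > 0) {
      ex <- ex + matrix(rnorm(length(ex), sd = spec$noise_sd_expr),
                        nrow(ex), ncol(ex))
    }

    geo <- place_features(spec, cpgs, genes, i2A, i2B, g2A, g2B)

    truth_cpgs <- data.table(
      cpg = cpgs[c(i1A, i1B, i2A, i2B)],
      cluster = rep(c("cluster1", "cluster2"),
                    c(length(i1A) + length(i1B), length(i2A) + length(i2B))),
      sub = rep(c("A", "B", "A", "B"),
                c(length(i1A), length(i1B), length(i2A), length(i2B))))
    truth_genes <- data.table(
      gene = genes[c(g1, g2A, g2B)],
      cluster = rep(c("cluster1", "cluster2"),
                    c(length(g1), length(g2A) + length(g2B))),
      # immune genes correlate negatively with 1A CpGs, so they are the "A"
      # direction of Cluster 1
      sub = rep(c("A", "A", "B"),
                c(length(g1), length(g2A), length(g2B))))

    structure(list(
      meth = meth, expr = ex,
      samples = data.table(sample = samples, er_status = er,
                           infiltration = f, purity = 1 - f),
      cpg_map = geo$cpg_map, gene_models = geo$gene_models,
      truth_cpgs = truth_cpgs, truth_genes = truth_genes,
      standard_genes = genes[g1],
      local_pair_genes = geo$local_pair_genes,
      spec = spec), class = "synthetic_cohort")
  })
}

# Place gene TSSs and CpG positions on the synthetic genome. A fraction of
# Cluster-2 genes receives one same-sub-cluster CpG within 10 kb of its TSS;
# every other Cluster-2 CpG is kept > 10 kb away from all Cluster-2 TSSs so
# the locally-paired gene fraction equals the configured value.
place_features <- function(spec, cpgs, genes, i2A, i2B, g2A, g2B) {
  nch <- spec$genome$n_chroms
  len <- spec$genome$chrom_length
  chrom_names <- paste0("chr", seq_len(nch))
  gene_chrom <- sample(chrom_names, length(genes), replace = TRUE)
  gene_tss <- floor(runif(length(genes), 0, len))
  gene_strand <- sample(c("+", "-"), length(genes), replace = TRUE)

  cpg_chrom <- sample(chrom_names, length(cpgs), replace = TRUE)
  cpg_pos <- floor(runif(length(cpgs), 0, len))

  g2 <- c(g2A, g2B)
  n_local <- round(spec$local_pair_fraction * length(g2))
  near_c2_tss <- function(chrom, pos) {
    any(gene_chrom[g2] == chrom & abs(gene_tss[g2] - pos) <= 10000)
  }
  # relocate every Cluster-2 CpG out of all Cluster-2 TSS windows
  for (i in c(i2A, i2B)) {
    while (near_c2_tss(cpg_chrom[i], cpg_pos[i])) {
      cpg_chrom[i] <- sample(chrom_names, 1L)
      cpg_pos[i] <- floor(runif(1L, 0, len))
    }
  }
  # then pull one partner CpG of the matching direction back beside each
  # locally-paired gene, choosing a position inside that gene's 10 kb window
  # but outside every other Cluster-2 gene's window; genes whose window is
  # fully shadowed by neighbours are skipped and another gene drawn instead
  partner_positions <- function(g) {
    cand <- max(0L, gene_tss[g] - 10000L):min(len - 1L, gene_tss[g] + 10000L)
    og <- setdiff(g2, g)
    og <- og[gene_chrom[og] == gene_chrom[g]]
    for (o in og) cand <- cand[abs(cand - gene_tss[o]) > 10000]
    cand
  }
  pool_A <- i2A; pool_B <- i2B
  local_genes <- integer(0)
  for (g in sample(g2)) {
    if (length(local_genes) >= n_local) break
    cand <- partner_positions(g)
    if (length(cand) == 0L) next
    pool <- if (g %in% g2A) pool_A else pool_B
    if (length(pool) == 0L) next
    i <- pool[1L]
    if (g %in% g2A) pool_A <- pool_A[-1L] else pool_B <- pool_B[-1L]
    cpg_chrom[i] <- gene_chrom[g]
    cpg_pos[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    local_genes <- c(local_genes, g)
  }
  list(cpg_map = data.table(cpg = cpgs, chrom = cpg_chrom,
                            pos = as.integer(cpg_pos)),
       gene_models = data.table(gene = genes, chrom = gene_chrom,
                                tss = as.integer(gene_tss),
                                strand = gene_strand),
       local_pair_genes = sort(genes[local_genes]))
}

#' Split a cohort into discovery and validation halves
#'
#' Samples are partitioned at random into two disjoint sets; both halves keep
#' the full feature space, optionally minus a random fraction of probes/genes
#' dropped from the validation half to emulate features that cannot be
#' re-tested in an independent cohort.
#'
#' @param cohort A [generate_cohort()] result.
#' @param discovery_fraction Fraction of samples assigned to discovery.
#' @param seed Integer seed for the split.
#' @param probe_drop_fraction,gene_drop_fraction Fractions of probes/genes
#'   removed from the validation half (recorded in `dropped`).
#' @return List with `discovery` and `validation` (each `meth`, `expr`,
#'   `samples`) and `dropped` (probe and gene ids missing from validation).
#' @export
split_cohort <- function(cohort, discovery_fraction = 0.5, seed = 1L,
                         probe_drop_fraction = 0, gene_drop_fraction = 0) {
  stopifnot(discovery_fraction > 0, discovery_fraction < 1)
  ns <- ncol(cohort$meth)
  n_disc <- round(discovery_fraction * ns)
  if (n_disc < 3L || ns - n_disc < 3L) {
    stop("each half needs >= 3 samples for correlation")
  }
  with_seed(seed, {
    disc <- sort(sample(ns, n_disc))
    vali <- setdiff(seq_len(ns), disc)
    drop_cpg <- character(0); drop_gene <- character(0)
    if (probe_drop_fraction > 0) {
      drop_cpg <- sample(rownames(cohort$meth),
                         round(probe_drop_fraction * nrow(cohort$meth)))
    }
    if (gene_drop_fraction > 0) {
      drop_gene <- sample(rownames(cohort$expr),
                          round(gene_drop_fraction * nrow(cohort$expr)))
    }
    take <- function(i, drop_c = character(0), drop_g = character(0)) {
      list(meth = cohort$meth[setdiff(rownames(cohort$meth), drop_c), i,
                              drop = FALSE],
           expr = cohort$expr[setdiff(rownames(cohort$expr), drop_g), i,
                              drop = FALSE],
           samples = cohort$samples[i])
    }
    list(discovery = take(disc),
         validation = take(vali, drop_cpg, drop_gene),
         dropped = list(cpgs = drop_cpg, genes = drop_gene))
  })
}

chromhmm_states <- c("Enhancer", "Enhancer+CTCF", "Promoter", "Promoter+CTCF",
                     "Poised Promoter", "Transcribed", "Repressed",
                     "Heterochromatin", "CTCF")

#' Generate annotation tracks matched to a synthetic cohort
#'
#' Builds a chromatin-state segmentation that tiles each chromosome without
#' gaps (planted clique CpGs land in Enhancer states), per-TF peak tracks
#' covering a configured fraction of Cluster-2A CpGs (plus sparse background
#' peaks), an immune-TF track over Cluster-1 CpGs, a super-enhancer track, and
#' a loop set connecting a fraction of planted (2A CpG, 2A gene) pairs.
#'
#' @param cohort A [generate_cohort()] result.
#' @param peak_fraction Per-track probability that a planted CpG gets a peak.
#' @param loop_support_fraction Fraction of (2A CpG, 2A gene) truth pairs
#'   connected by a loop.
#' @param tile_width Segmentation tile width (bp).
#' @param n_background_peaks Random decoy peaks per TF track; the default
#'   scales with genome length (1 peak per ~67 kb) so the background CpG hit
#'   rate stays low at any genome size.
#' @param seed Integer seed (independent of the cohort seed).
#' @return List of class `synthetic_annotations` with `segmentation`,
#'   `peaks` (named list of tracks: ERA, FOXA1, GATA3, CTCF, IMMUNE_TF),
#'   `super_enhancers` and `loops`.
#' @export
generate_annotations <- function(cohort, peak_fraction = 0.8,
                                 loop_support_fraction = 0.25,
                                 tile_width = 1000L,
                                 n_background_peaks = NULL,
                                 seed = cohort$spec$seed + 1000L) {
  spec <- cohort$spec
  len <- spec$genome$chrom_length
  if (len < 2 * tile_width) stop("chromosome too short to tile")
  if (is.null(n_background_peaks)) {
    n_background_peaks <- max(10L, round(spec$genome$n_chroms * len / 67000))
  }
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(spec$genome$n_chroms))
    n_tiles <- ceiling(len / tile_width)
    state_prob <- c(0.06, 0.02, 0.06, 0.02, 0.02, 0.20, 0.15, 0.37, 0.10)
    seg <- data.table(
      chrom = rep(chroms, each = n_tiles),
      start = rep(as.integer((seq_len(n_tiles) - 1L) * tile_width), length(chroms)),
      end = rep(as.integer(pmin(seq_len(n_tiles) * tile_width, len)), length(chroms)),
      label = sample(chromhmm_states, n_tiles * length(chroms),
                     replace = TRUE, prob = state_prob))
    # force tiles holding planted clique CpGs into enhancer states
    planted <- cohort$truth_cpgs$cpg
    pm <- cohort$cpg_map[match(planted, cohort$cpg_map$cpg)]
    tile_of <- (pm$pos %/% tile_width) + 1L
    row_of <- match(pm$chrom, chroms)
    seg_idx <- (row_of - 1L) * n_tiles + tile_of
    seg$label[seg_idx] <- sample(c("Enhancer", "Enhancer+CTCF"),
                                 length(seg_idx), replace = TRUE,
                                 prob = c(0.8, 0.2))

    cpg2A <- cohort$truth_cpgs[cohort$truth_cpgs$cluster == "cluster2" &
                                 cohort$truth_cpgs$sub == "A", ]$cpg
    cpg1 <- cohort$truth_cpgs[cohort$truth_cpgs$cluster == "cluster1", ]$cpg
    peak_at <- function(ids, label) {
      m <- cohort$cpg_map[match(ids, cohort$cpg_map$cpg)]
      data.table(chrom = m$chrom,
                 start = as.integer(pmax(0, m$pos - 150L)),
                 end = as.integer(m$pos + 250L),
                 label = label)
    }
    random_peaks <- function(n, label, width = 400L) {
      data.table(chrom = sample(chroms, n, replace = TRUE),
                 start = as.integer(floor(runif(n, 0, len - width))),
                 end = NA_integer_, label = label)[, end := start + width][]
    }
    tf_track <- function(name, at_ids) {
      sel <- at_ids[runif(length(at_ids)) < peak_fraction]
      rbind(peak_at(sel, name), random_peaks(n_background_peaks, name))
    }
    peaks <- list(
      ERA = tf_track("ERA", cpg2A),
      FOXA1 = tf_track("FOXA1", cpg2A),
      GATA3 = tf_track("GATA3", cpg2A),
      CTCF = random_peaks(500L, "CTCF"),
      IMMUNE_TF = tf_track("IMMUNE_TF", cpg1))

    se_ids <- cpg2A[runif(length(cpg2A)) < 0.3]
    sem <- cohort$cpg_map[match(se_ids, cohort$cpg_map$cpg)]
    super_enhancers <- data.table(
      chrom = sem$chrom,
      start = as.integer(pmax(0, sem$pos - 5000L)),
      end = as.integer(sem$pos + 5000L),
      label = paste0("SE_", seq_along(se_ids)))

    g2A <- cohort$truth_genes[cohort$truth_genes$cluster == "cluster2" &
                                cohort$truth_genes$sub == "A", ]$gene
    all_pairs <- expand.grid(cpg = cpg2A, gene = g2A,
                             stringsAsFactors = FALSE)
    n_loops <- round(loop_support_fraction * nrow(all_pairs))
    sel <- sample(nrow(all_pairs), n_loops)
    lc <- cohort$cpg_map[match(all_pairs$cpg[sel], cohort$cpg_map$cpg)]
    lg <- cohort$gene_models[match(all_pairs$gene[sel],
                                   cohort$gene_models$gene)]
    loops <- data.table(
      loop_id = paste0("loop_", seq_len(n_loops)),
      chromA = lc$chrom, startA = as.integer(pmax(0, lc$pos - 500L)),
      endA = as.integer(lc$pos + 500L),
      chromB = lg$chrom, startB = as.integer(pmax(0, lg$tss - 500L)),
      endB = as.integer(lg$tss + 500L))
    # randomise anchor orientation; loop support must be symmetric
    flip <- runif(n_loops) < 0.5
    if (any(flip)) {
      for (ab in list(c("chromA", "chromB"), c("startA", "startB"),
                      c("endA", "endB"))) {
        tmp <- loops[[ab[1L]]][flip]
        data.table::set(loops, which(flip), ab[1L], loops[[ab[2L]]][flip])
        data.table::set(loops, which(flip), ab[2L], tmp)
      }
    }
    decoys <- data.table(
      loop_id = paste0("decoy_", seq_len(200L)),
      chromA = sample(chroms, 200L, replace = TRUE),
      startA = as.integer(floor(runif(200L, 0, len - 1000L))),
      chromB = sample(chroms, 200L, replace = TRUE),
      startB = as.integer(floor(runif(200L, 0, len - 1000L))))
    decoys[, `:=`(endA = startA + 1000L, endB = startB + 1000L)]
    loops <- rbind(loops, decoys[, names(loops), with = FALSE])

    structure(list(segmentation = seg, peaks = peaks,
                   super_enhancers = super_enhancers, loops = loops),
              class = "synthetic_annotations")
  })
}
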