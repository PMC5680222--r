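# Stage-based orchestration of the full analysis on one output directory:
# simulate -> discover -> validate -> cluster -> enrich -> infiltration ->
# report. Each stage reads the files earlier stages wrote, so any stage can
# be re-run in isolation; re-running with the same config reproduces the
# same outputs.

#' Pipeline configuration
#'
#' Bundles the analysis constants (IQR cutoff 0.1, family-wise alpha 0.05,
#' +/- 200 bp peak windows, 10 kb cis distance, 1000 permutations, 0.1
#' minimum median methylation difference), the cohort generator spec, the
#' output directory and one global seed from which each stage derives its
#' own.
#'
#' @param out_dir Output directory (created on first use).
#' @param spec A [cohort_spec()] for the simulate stage.
#' @param min_iqr,alpha,window,local_dist,n_perm,min_median_diff Analysis
#'   thresholds.
#' @param cap Cap on `-log10(p)` in the significance matrix.
#' @param discovery_fraction Sample fraction assigned to discovery.
#' @param probe_drop_fraction Probes removed from the validation half.
#' @param k_rows,k_cols Bicluster cut sizes or `"auto"`.
#' @param seed Global integer seed.
#' @return List of class `emqtl_config`.
#' @export
emqtl_config <- function(out_dir, spec = cohort_spec(),
                         min_iqr = 0.1, alpha = 0.05, window = 200L,
                         local_dist = 10000L, n_perm = 1000L,
                         min_median_diff = 0.1, cap = 300,
                         discovery_fraction = 0.5,
                         probe_drop_fraction = 0.05,
                         k_rows = "auto", k_cols = "auto",
                         seed = 1L) {
  stopifnot(min_iqr > 0, alpha > 0, window >= 0, local_dist > 0, n_perm >= 1,
            min_median_diff > 0)
  structure(list(out_dir = out_dir, spec = spec, min_iqr = min_iqr,
                 alpha = alpha, window = as.integer(window),
                 local_dist = as.integer(local_dist),
                 n_perm = as.integer(n_perm),
                 min_median_diff = min_median_diff, cap = cap,
                 discovery_fraction = discovery_fraction,
                 probe_drop_fraction = probe_drop_fraction,
                 k_rows = k_rows, k_cols = k_cols, seed = as.integer(seed)),
            class = "emqtl_config")
}

# per-stage seeds derived deterministically from the global seed
stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, split = 23L, annotations = 37L,
               permutation = 53L)
  (config$seed * 101L + offsets[[stage]]) %% 2147483647L
}

# polynomial rolling hash of the semantic config fields (paths excluded)
config_hash <- function(config) {
  sem <- config[setdiff(names(config), "out_dir")]
  bytes <- utf8ToInt(yaml::as.yaml(sem))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pth <- function(config, ...) file.path(config$out_dir, ...)

need <- function(config, files, prior_stage) {
  missing <- files[!file.exists(file.path(config$out_dir, files))]
  if (length(missing)) {
    stop("missing ", paste(missing, collapse = ", "),
         "; run stage '", prior_stage, "' first")
  }
}

log_stage <- function(config, stage, files, seed = NA_integer_) {
  mf <- pth(config, "manifest.tsv")
  entry <- data.table(stage = stage, file = files, seed = seed,
                      config_hash = config_hash(config))
  old <- if (file.exists(mf)) fread(mf)[stage != entry$stage[1L]] else NULL
  fwrite(rbind(old, entry), mf, sep = "\t")
  invisible(entry)
}

#' Run one pipeline stage
#'
#' @param name One of `"simulate"`, `"discover"`, `"validate"`, `"cluster"`,
#'   `"enrich"`, `"infiltration"`, `"report"`.
#' @param config An [emqtl_config()].
#' @return The stage's main result, invisibly; outputs land in
#'   `config$out_dir` and are recorded in `manifest.tsv`.
#' @export
run_stage <- function(name, config) {
  name <- match.arg(name, c("simulate", "discover", "validate", "cluster",
                            "enrich", "infiltration", "report"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(config),
         discover = stage_discover(config),
         validate = stage_validate(config),
         cluster = stage_cluster(config),
         enrich = stage_enrich(config),
         infiltration = stage_infiltration(config),
         report = stage_report(config))
}

#' Run the full pipeline
#'
#' @param config An [emqtl_config()].
#' @return Named list of every stage's result.
#' @export
run_pipeline <- function(config) {
  stages <- c("simulate", "discover", "validate", "cluster", "enrich",
              "infiltration", "report")
  setNames(lapply(stages, run_stage, config = config), stages)
}

stage_simulate <- function(config) {
  spec <- config$spec
  spec$seed <- stage_seed(config, "simulate")
  spec <- do.call(cohort_spec, spec[setdiff(names(spec), NULL)])
  cohort <- generate_cohort(spec)
  halves <- split_cohort(cohort, config$discovery_fraction,
                         seed = stage_seed(config, "split"),
                         probe_drop_fraction = config$probe_drop_fraction)
  ann <- generate_annotations(cohort, seed = stage_seed(config, "annotations"))
  p <- function(...) pth(config, ...)
  write_numeric_matrix(halves$discovery$meth, p("discovery_meth.tsv"))
  write_numeric_matrix(halves$discovery$expr, p("discovery_expr.tsv"))
  write_numeric_matrix(halves$validation$meth, p("validation_meth.tsv"))
  write_numeric_matrix(halves$validation$expr, p("validation_expr.tsv"))
  write_numeric_matrix(cohort$meth, p("meth.tsv"))
  write_numeric_matrix(cohort$expr, p("expr.tsv"))
  fwrite(cohort$samples, p("samples.tsv"), sep = "\t")
  fwrite(cohort$cpg_map, p("cpg_map.tsv"), sep = "\t")
  fwrite(cohort$gene_models, p("gene_models.tsv"), sep = "\t")
  fwrite(cohort$truth_cpgs, p("truth_cpgs.tsv"), sep = "\t")
  fwrite(cohort$truth_genes, p("truth_genes.tsv"), sep = "\t")
  writeLines(cohort$standard_genes, p("standard_genes.txt"))
  writeLines(cohort$local_pair_genes, p("local_pair_genes.txt"))
  write_interval_track(ann$segmentation, p("segmentation.bed"))
  for (nm in names(ann$peaks)) {
    write_interval_track(ann$peaks[[nm]], p(paste0("peaks_", nm, ".bed")))
  }
  write_interval_track(ann$super_enhancers, p("super_enhancers.bed"))
  write_loops(ann$loops, p("loops.bedpe"))
  files <- c("discovery_meth.tsv", "discovery_expr.tsv", "validation_meth.tsv",
             "validation_expr.tsv", "meth.tsv", "expr.tsv", "samples.tsv",
             "cpg_map.tsv", "gene_models.tsv", "truth_cpgs.tsv",
             "truth_genes.tsv", "standard_genes.txt", "local_pair_genes.txt",
             "segmentation.bed",
             paste0("peaks_", names(ann$peaks), ".bed"),
             "super_enhancers.bed", "loops.bedpe")
  log_stage(config, "simulate", files, stage_seed(config, "simulate"))
  invisible(list(cohort = cohort, halves = halves, annotations = ann))
}

stage_discover <- function(config) {
  need(config, c("discovery_meth.tsv", "discovery_expr.tsv"), "simulate")
  meth <- read_numeric_matrix(pth(config, "discovery_meth.tsv"))
  expr <- read_numeric_matrix(pth(config, "discovery_expr.tsv"))
  keep <- iqr_filter(meth, config$min_iqr)
  res <- all_pair_emqtl(meth[keep$retained, , drop = FALSE], expr,
                        alpha = config$alpha)
  write_emqtl_pairs(res, pth(config, "discovery_pairs.tsv.gz"))
  yaml::write_yaml(list(stage = "discover", n_cpgs_tested = res$n_cpg_tested,
                        n_genes_tested = res$n_gene_tested,
                        m = res$m, alpha = res$alpha,
                        n_pairs = nrow(res$pairs)),
                   pth(config, "discovery_summary.yaml"))
  log_stage(config, "discover",
            c("discovery_pairs.tsv.gz", "discovery_summary.yaml"))
  invisible(res)
}

stage_validate <- function(config) {
  need(config, "discovery_pairs.tsv.gz", "discover")
  need(config, c("validation_meth.tsv", "validation_expr.tsv"), "simulate")
  disc <- read_emqtl_pairs(pth(config, "discovery_pairs.tsv.gz"))
  meth2 <- read_numeric_matrix(pth(config, "validation_meth.tsv"))
  expr2 <- read_numeric_matrix(pth(config, "validation_expr.tsv"))
  res <- validate_pairs(disc, meth2, expr2, alpha = config$alpha)
  write_emqtl_pairs(res, pth(config, "validated_pairs.tsv.gz"))
  yaml::write_yaml(c(list(stage = "validate"), res$summary),
                   pth(config, "validation_summary.yaml"))
  log_stage(config, "validate",
            c("validated_pairs.tsv.gz", "validation_summary.yaml"))
  invisible(res)
}

stage_cluster <- function(config) {
  need(config, "validated_pairs.tsv.gz", "validate")
  res <- read_emqtl_pairs(pth(config, "validated_pairs.tsv.gz"))
  sig <- significance_matrix(res, cap = config$cap)
  trees <- cocluster(sig)
  bcs <- extract_biclusters(trees, sig, config$k_rows, config$k_cols)
  bcs <- lapply(bcs, split_by_direction, sig = sig)
  write_biclusters(bcs, pth(config, "biclusters.tsv"))
  writeLines(c(hclust_newick(trees$row_tree), hclust_newick(trees$col_tree)),
             pth(config, "dendrograms.nwk"))
  log_stage(config, "cluster", c("biclusters.tsv", "dendrograms.nwk"))
  invisible(list(sig = sig, trees = trees, biclusters = bcs))
}

# minimal Newick serialisation of an hclust tree
hclust_newick <- function(h) {
  rec <- function(i) {
    if (i < 0) return(h$labels[-i])
    sprintf("(%s:%f,%s:%f)", rec(h$merge[i, 1L]), h$height[i],
            rec(h$merge[i, 2L]), h$height[i])
  }
  paste0(rec(nrow(h$merge)), ";")
}

read_biclusters <- function(path) {
  d <- fread(path, sep = "\t")
  lapply(split(d, d$cluster), function(x) {
    bc <- list(label = x$cluster[1L],
               cpg_ids = x$id[x$type == "cpg"],
               gene_ids = x$id[x$type == "gene"],
               cpg_sub = setNames(x$sub_cluster[x$type == "cpg"],
                                  x$id[x$type == "cpg"]),
               gene_sub = setNames(x$sub_cluster[x$type == "gene"],
                                   x$id[x$type == "gene"]))
    structure(bc, class = "bicluster")
  })
}

stage_enrich <- function(config) {
  need(config, "biclusters.tsv", "cluster")
  need(config, c("cpg_map.tsv", "gene_models.tsv", "segmentation.bed",
                 "loops.bedpe"), "simulate")
  bcs <- read_biclusters(pth(config, "biclusters.tsv"))
  cpg_map <- fread(pth(config, "cpg_map.tsv"))
  gene_models <- fread(pth(config, "gene_models.tsv"))
  seg <- read_interval_track(pth(config, "segmentation.bed"))
  loops <- read_loops(pth(config, "loops.bedpe"))
  peak_files <- list.files(config$out_dir, pattern = "^peaks_.*\\.bed$")
  peaks <- lapply(file.path(config$out_dir, peak_files), read_interval_track)
  names(peaks) <- sub("^peaks_(.*)\\.bed$", "\\1", peak_files)
  vali <- read_emqtl_pairs(pth(config, "validated_pairs.tsv.gz"))
  background <- cpg_map$cpg

  out <- list()
  for (bc in bcs) {
    states <- chromhmm_profile(bc$cpg_ids, cpg_map, seg, background)
    states[, `:=`(cluster = bc$label, analysis = "chromhmm")]
    pk <- data.table::rbindlist(lapply(names(peaks), function(nm) {
      peak_enrichment(bc$cpg_ids, cpg_map, peaks[[nm]], background,
                      half_width = config$window, category = nm)
    }))
    pk[, `:=`(cluster = bc$label, analysis = "peaks")]
    out[[bc$label]] <- rbind(states, pk)
  }
  enr <- data.table::rbindlist(out)
  fwrite(enr, pth(config, "enrichment.tsv"), sep = "\t")

  # permutation test of the second clique's CpGs vs the lineage-TF union
  tf_union <- peaks[intersect(names(peaks), c("ERA", "FOXA1", "GATA3"))]
  perm <- NULL
  if (length(bcs) >= 1L && length(tf_union)) {
    target <- bcs[[length(bcs)]]  # by-size labelling: last = Cluster2-like
    # choose the clique whose CpGs hit the TF union most
    hit_frac <- vapply(bcs, function(bc) {
      mean(peak_hits(bc$cpg_ids, cpg_map, data.table::rbindlist(tf_union), 0))
    }, numeric(1L))
    target <- bcs[[which.max(hit_frac)]]
    perm <- permutation_enrichment(target$cpg_ids, cpg_map, tf_union,
                                   background, n_perm = config$n_perm,
                                   seed = stage_seed(config, "permutation"))
    fwrite(data.table(cluster = target$label, observed = perm$observed,
                      n_perm = perm$n_perm, p = perm$p),
           pth(config, "permutation.tsv"), sep = "\t")
    lp <- local_pairs(vali$pairs[vali$pairs$cpg %in% target$cpg_ids &
                                   vali$pairs$gene %in% target$gene_ids, ],
                      cpg_map, gene_models, config$local_dist)
    le <- loop_enrichment(
      vali$pairs[vali$pairs$cpg %in% target$cpg_ids &
                   vali$pairs$gene %in% target$gene_ids, c("cpg", "gene")],
      loops, cpg_map, gene_models, vali$pairs[, c("cpg", "gene")])
    fwrite(data.table(cluster = target$label,
                      local_gene_fraction = lp$local_gene_fraction,
                      loop_ratio = le$ratio, loop_p = le$p),
           pth(config, "cis_and_loops.tsv"), sep = "\t")
  }
  log_stage(config, "enrich",
            c("enrichment.tsv", "permutation.tsv", "cis_and_loops.tsv"))
  invisible(list(enrichment = enr, permutation = perm))
}

stage_infiltration <- function(config) {
  need(config, c("expr.tsv", "meth.tsv", "standard_genes.txt"), "simulate")
  need(config, "biclusters.tsv", "cluster")
  expr <- read_numeric_matrix(pth(config, "expr.tsv"))
  meth <- read_numeric_matrix(pth(config, "meth.tsv"))
  std <- readLines(pth(config, "standard_genes.txt"))
  bcs <- read_biclusters(pth(config, "biclusters.tsv"))
  scores <- infiltration_score(expr, std)
  groups <- quartile_groups(scores)
  fwrite(data.table(sample = scores$sample, score = scores$score,
                    quartile = as.character(groups[scores$sample])),
         pth(config, "infiltration_scores.tsv"), sep = "\t")
  # trend of the clique holding the standard genes (the immune clique)
  imm <- bcs[[which.max(vapply(bcs, function(b) length(intersect(b$gene_ids, std)),
                               numeric(1L)))]]
  trends <- lapply(c(A = "A", B = "B"), function(s) {
    ids <- names(imm$cpg_sub)[imm$cpg_sub == s]
    if (length(ids) == 0L) return(NULL)
    infiltration_methylation_trend(meth, ids, groups)
  })
  tr <- data.table::rbindlist(lapply(names(trends), function(s) {
    t <- trends[[s]]
    if (is.null(t)) return(NULL)
    data.table(sub_cluster = s, trend = t$trend,
               q1 = t$group_means[[1]], q2 = t$group_means[[2]],
               q3 = t$group_means[[3]], q4 = t$group_means[[4]],
               kw_h = t$test$H, kw_p = t$test$p)
  }))
  fwrite(tr, pth(config, "infiltration_trends.tsv"), sep = "\t")
  log_stage(config, "infiltration",
            c("infiltration_scores.tsv", "infiltration_trends.tsv"))
  invisible(list(scores = scores, groups = groups, trends = trends))
}

stage_report <- function(config) {
  need(config, c("discovery_summary.yaml", "validation_summary.yaml"),
       "validate")
  ds <- yaml::read_yaml(pth(config, "discovery_summary.yaml"))
  vs <- yaml::read_yaml(pth(config, "validation_summary.yaml"))
  lines <- c(
    "emQTL pipeline report",
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("thresholds: min_iqr=%g alpha=%g window=%d local_dist=%d n_perm=%d",
            config$min_iqr, config$alpha, config$window, config$local_dist,
            config$n_perm),
    sprintf("discovery: %d CpGs x %d genes tested, %d significant pairs",
            ds$n_cpgs_tested, ds$n_genes_tested, ds$n_pairs),
    sprintf("validation: input=%d untestable=%d testable=%d validated=%d rate=%.4f",
            vs$n_input, vs$n_untestable, vs$n_testable, vs$n_validated,
            vs$validation_rate))
  if (file.exists(pth(config, "biclusters.tsv"))) {
    bcs <- read_biclusters(pth(config, "biclusters.tsv"))
    lines <- c(lines, sprintf("cliques: %d", length(bcs)))
    for (bc in bcs) {
      lines <- c(lines, sprintf(
        "  %s: %d CpGs (%d A / %d B), %d genes (%d A / %d B)",
        bc$label, length(bc$cpg_ids), sum(bc$cpg_sub == "A"),
        sum(bc$cpg_sub == "B"), length(bc$gene_ids),
        sum(bc$gene_sub == "A"), sum(bc$gene_sub == "B")))
    }
  }
  if (file.exists(pth(config, "cis_and_loops.tsv"))) {
    cl <- fread(pth(config, "cis_and_loops.tsv"))
    lines <- c(lines, sprintf(
      "cis/loops [%s]: local_gene_fraction=%.4f loop_ratio=%.3f loop_p=%.3g",
      cl$cluster[1], cl$local_gene_fraction[1], cl$loop_ratio[1], cl$loop_p[1]))
  }
  if (file.exists(pth(config, "infiltration_trends.tsv"))) {
    tr <- fread(pth(config, "infiltration_trends.tsv"))
    for (i in seq_len(nrow(tr))) {
      lines <- c(lines, sprintf(
        "infiltration trend %s: %s (KW p=%.3g)", tr$sub_cluster[i],
        tr$trend[i], tr$kw_p[i]))
    }
  }
  writeLines(lines, pth(config, "report.txt"))
  log_stage(config, "report", "report.txt")
  invisible(lines)
}
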