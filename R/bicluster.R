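# Hierarchical co-clustering of the CpG x gene significance matrix and
# extraction of dense cliques with directional (A/B) sub-clusters.

#' Build the CpG-by-gene significance matrix
#'
#' Rows are CpGs and columns genes with at least one significant pair; each
#' entry is `-log10(p_bonf)` capped at `cap` (zero where the pair is not
#' significant). The signed variant multiplies by the correlation sign so the
#' direction of each association is retained for sub-cluster labelling.
#'
#' @param results An `emqtl_result` (validation stage by convention;
#'   discovery works too).
#' @param cap Cap for `-log10(p_bonf)`; p-values that underflow to zero take
#'   the cap (default 300).
#' @return List of class `significance_matrix` with `value` and `signed`
#'   matrices.
#' @export
significance_matrix <- function(results, cap = 300) {
  d <- results$pairs
  if (nrow(d) == 0L) stop("no significant pairs to cluster")
  cpgs <- sort(unique(d$cpg)); genes <- sort(unique(d$gene))
  v <- -log10(pmax(d$p_bonf, 10^(-cap)))
  v <- pmin(v, cap)
  m <- matrix(0, length(cpgs), length(genes), dimnames = list(cpgs, genes))
  s <- m
  ij <- cbind(match(d$cpg, cpgs), match(d$gene, genes))
  m[ij] <- v
  s[ij] <- ifelse(d$sign == "negative", -v, v)
  structure(list(value = m, signed = s, cap = cap),
            class = "significance_matrix")
}

# correlation distance between rows; constant rows get distance 1 to
# everything (correlation undefined), keeping them in the tree
cor_dist <- function(m) {
  sds <- apply(m, 1L, stats::sd)
  d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  ok <- which(sds > 0)
  if (length(ok) >= 2L) {
    d[ok, ok] <- 1 - cor(t(m[ok, , drop = FALSE]))
  }
  diag(d) <- 0
  as.dist(d)
}

#' Co-cluster the significance matrix
#'
#' Rows (CpGs) and columns (genes) are clustered independently with the
#' one-minus-Pearson correlation distance over the full profile (zeros
#' included) and average linkage.
#'
#' @param sig A [significance_matrix()] (or a plain matrix).
#' @param linkage Agglomeration method (default `"average"`).
#' @return List with `row_tree` and `col_tree` (`hclust` objects).
#' @export
cocluster <- function(sig, linkage = "average") {
  m <- if (inherits(sig, "significance_matrix")) sig$value else sig
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and >= 2 columns")
  list(row_tree = hclust(cor_dist(m), method = linkage),
       col_tree = hclust(cor_dist(t(m)), method = linkage))
}

# candidate cliques for one (k_rows, k_cols) cut
cut_cliques <- function(trees, m, k_rows, k_cols) {
  rg <- cutree(trees$row_tree, k = k_rows)
  cg <- cutree(trees$col_tree, k = k_cols)
  cliques <- lapply(sort(unique(rg)), function(r) {
    rows <- names(rg)[rg == r]
    means <- vapply(sort(unique(cg)), function(cc) {
      mean(m[rows, names(cg)[cg == cc], drop = FALSE])
    }, numeric(1L))
    best <- which.max(means)
    list(cpg_ids = rows, gene_ids = names(cg)[cg == sort(unique(cg))[best]],
         density = means[best])
  })
  cliques
}

# cut quality: cell-weighted mean value inside the cliques minus the mean
# value outside them (weighting stops the scan from shaving weak members off
# a clique merely to raise an unweighted density average)
clique_score <- function(cliques, m) {
  inside <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (cl in cliques) inside[cl$cpg_ids, cl$gene_ids] <- TRUE
  within <- mean(m[inside])
  between <- if (all(inside)) 0 else mean(m[!inside])
  within - between
}

#' Extract dense biclusters (cliques) from the co-clustered matrix
#'
#' Cuts the row tree into `k_rows` groups and the column tree into `k_cols`
#' groups, matches every row group with the column group maximising the mean
#' in-clique significance, and keeps candidates denser than the overall
#' matrix mean. With `"auto"` the cut is chosen by scanning k in 2..10 and
#' maximising mean within-clique density minus the mean outside the cliques.
#' Cliques are labelled `Cluster1`, `Cluster2`, ... by decreasing size
#' (number of matrix cells).
#'
#' @param trees Output of [cocluster()].
#' @param sig The clustered [significance_matrix()] (or plain matrix).
#' @param k_rows,k_cols Number of groups, or `"auto"`.
#' @param min_rows,min_cols Minimum clique dimensions; candidates with a
#'   single CpG or gene are degenerate (one stray significant pair can form
#'   them) and are dropped by default.
#' @return List of `bicluster` objects (`label`, `cpg_ids`, `gene_ids`,
#'   `density`).
#' @export
extract_biclusters <- function(trees, sig, k_rows = "auto", k_cols = "auto",
                               min_rows = 2L, min_cols = 2L) {
  m <- if (inherits(sig, "significance_matrix")) sig$value else sig
  kr_opts <- if (identical(k_rows, "auto"))
    seq.int(2L, min(10L, nrow(m))) else as.integer(k_rows)
  kc_opts <- if (identical(k_cols, "auto"))
    seq.int(2L, min(10L, ncol(m))) else as.integer(k_cols)
  if (any(kr_opts > nrow(m)) || any(kc_opts > ncol(m))) {
    stop("k exceeds matrix dimension")
  }
  best <- NULL; best_score <- -Inf
  for (kr in kr_opts) for (kc in kc_opts) {
    cl <- cut_cliques(trees, m, kr, kc)
    sc <- clique_score(cl, m)
    if (sc > best_score + 1e-12) {
      best <- cl; best_score <- sc
    }
  }
  bg <- mean(m)
  keep <- Filter(function(cl) {
    cl$density > bg && length(cl$cpg_ids) >= min_rows &&
      length(cl$gene_ids) >= min_cols
  }, best)
  if (length(keep) == 0L) keep <- best[which.max(vapply(best, `[[`, numeric(1L), "density"))]
  sizes <- vapply(keep, function(cl) length(cl$cpg_ids) * length(cl$gene_ids),
                  numeric(1L))
  keep <- keep[order(-sizes)]
  for (i in seq_along(keep)) {
    keep[[i]]$label <- paste0("Cluster", i)
    keep[[i]] <- structure(keep[[i]], class = "bicluster")
  }
  keep
}

#' Split a bicluster into directional sub-clusters A and B
#'
#' A CpG is labelled `A` when its mean signed significance across the
#' clique's genes is negative (methylation anti-correlated with clique gene
#' expression) and `B` otherwise; a zero mean ties to `A`. Genes are labelled
#' `A` when their mean signed value across the A CpGs is negative, `B`
#' otherwise (all genes fall in `B` if no CpG is labelled `A`).
#'
#' @param bc A `bicluster`.
#' @param sig The [significance_matrix()] carrying the signed variant.
#' @return The bicluster with `cpg_sub` and `gene_sub` named label vectors.
#' @export
split_by_direction <- function(bc, sig) {
  s <- sig$signed[bc$cpg_ids, bc$gene_ids, drop = FALSE]
  cpg_mean <- rowMeans(s)
  cpg_sub <- ifelse(cpg_mean <= 0, "A", "B")
  a_cpgs <- names(cpg_sub)[cpg_sub == "A"]
  gene_sub <- if (length(a_cpgs)) {
    ifelse(colMeans(s[a_cpgs, , drop = FALSE]) < 0, "A", "B")
  } else {
    setNames(rep("B", ncol(s)), colnames(s))
  }
  bc$cpg_sub <- setNames(cpg_sub, rownames(s))
  bc$gene_sub <- setNames(gene_sub, colnames(s))
  bc
}

#' Hierarchically cluster samples on a feature subset
#'
#' Euclidean distance over the selected feature rows, average linkage.
#'
#' @param m Feature-by-sample matrix.
#' @param features Feature ids selecting the rows used.
#' @return List with `tree` (`hclust`) and `order` (sample ids in dendrogram
#'   order).
#' @export
cluster_samples <- function(m, features) {
  features <- intersect(features, rownames(m))
  if (length(features) == 0L) stop("feature set disjoint from matrix rows")
  if (ncol(m) < 2L) stop("need >= 2 samples")
  tree <- hclust(dist(t(m[features, , drop = FALSE])), method = "average")
  list(tree = tree, order = colnames(m)[tree$order])
}

#' Pairwise absolute co-correlation within a member set
#'
#' All pairwise `|Pearson r|` between the member rows across samples, e.g.
#' the co-methylation of a clique's CpGs or co-expression of its genes.
#'
#' @param m Feature-by-sample matrix.
#' @param members Row ids (>= 2 present in `m`).
#' @return Numeric vector of the upper-triangle `|r|` values.
#' @export
cocorrelation_density <- function(m, members) {
  members <- intersect(members, rownames(m))
  if (length(members) < 2L) stop("need >= 2 members")
  cc <- abs(cor(t(m[members, , drop = FALSE])))
  cc[upper.tri(cc)]
}

#' Write bicluster memberships as TSV
#'
#' @param biclusters List of labelled biclusters (after
#'   [split_by_direction()], if sub-labels are wanted).
#' @param path Output TSV path.
#' @export
write_biclusters <- function(biclusters, path) {
  rows <- lapply(biclusters, function(bc) {
    sub_c <- if (!is.null(bc$cpg_sub)) bc$cpg_sub[bc$cpg_ids] else NA_character_
    sub_g <- if (!is.null(bc$gene_sub)) bc$gene_sub[bc$gene_ids] else NA_character_
    rbind(data.table(id = bc$cpg_ids, type = "cpg", cluster = bc$label,
                     sub_cluster = as.character(sub_c)),
          data.table(id = bc$gene_ids, type = "gene", cluster = bc$label,
                     sub_cluster = as.character(sub_g)))
  })
  fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}
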