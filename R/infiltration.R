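# Lymphocyte-infiltration scoring from expression of a lymphocyte-specific
# "standard gene" signature, quartile grouping, and the nonparametric group
# statistics used downstream.

#' Score samples for lymphocyte infiltration
#'
#' The score is the per-sample mean expression of the standard genes found in
#' the matrix; absent standard genes are reported, and an error is raised
#' only when none is present.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param standard_genes Lymphocyte-specific signature gene ids.
#' @return `data.table(sample, score)` with attribute `missing_genes`.
#' @export
infiltration_score <- function(expr, standard_genes) {
  present <- intersect(standard_genes, rownames(expr))
  if (length(present) == 0L) stop("no standard genes found in the matrix")
  score <- colMeans(expr[present, , drop = FALSE], na.rm = TRUE)
  out <- data.table(sample = colnames(expr), score = as.numeric(score))
  attr(out, "missing_genes") <- setdiff(standard_genes, present)
  out
}

#' Quartile groups of a score
#'
#' Samples are ranked (ties broken by their input order, keeping the grouping
#' stable) and split at the 25/50/75% rank cut points into `Q1` (lowest) to
#' `Q4`; group sizes differ by at most one.
#'
#' @param scores `data.table(sample, score)` from [infiltration_score()], or
#'   a named numeric vector.
#' @return Factor of labels `Q1..Q4` named by sample.
#' @export
quartile_groups <- function(scores) {
  if (is.data.frame(scores)) {
    v <- setNames(scores$score, scores$sample)
  } else v <- scores
  n <- length(v)
  if (n < 4L) stop("need >= 4 samples for quartile groups")
  if (length(unique(v)) == 1L) {
    warning("all scores equal; quartile groups follow sample order")
  }
  rk <- order(order(v, seq_len(n)))  # ranks, ties by stable input order
  grp <- floor((rk - 1) * 4 / n) + 1
  factor(setNames(paste0("Q", grp), names(v)), levels = paste0("Q", 1:4))
}

#' Kruskal-Wallis comparison of a value across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test with the chi-square upper-tail
#' p-value on `groups - 1` degrees of freedom, plus group medians.
#'
#' @param values Numeric vector.
#' @param groups Group labels, parallel to `values`.
#' @return List of class `group_comparison`: `H`, `df`, `p`,
#'   `group_medians`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (length(unique(values)) == 1L) {
    kt <- list(statistic = c(H = 0), parameter = nlevels(groups) - 1,
               p.value = 1)
  } else {
    kt <- kruskal.test(values, groups)
  }
  med <- tapply(values, groups, median)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value,
                 group_medians = setNames(as.numeric(med), names(med))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %g, p = %.3g\n",
              x$H, x$df, x$p))
  invisible(x)
}

#' Per-sample mean over a feature set
#'
#' Mean of the selected feature rows per sample, excluding missing values,
#' e.g. the average methylation of a CpG cluster.
#'
#' @param m Feature-by-sample matrix.
#' @param features Row ids (their intersection with the matrix is used).
#' @return Named numeric vector (one mean per sample).
#' @export
set_average <- function(m, features) {
  features <- intersect(features, rownames(m))
  if (length(features) == 0L) stop("feature set disjoint from matrix rows")
  colMeans(m[features, , drop = FALSE], na.rm = TRUE)
}

#' Methylation trend of a CpG set across infiltration quartiles
#'
#' Averages the CpG set per sample, summarises the mean per quartile group,
#' reports whether the Q1..Q4 sequence is strictly monotone (decreasing,
#' increasing, or neither), and tests the per-sample averages across groups
#' by Kruskal-Wallis.
#'
#' @param meth CpG-by-sample beta matrix.
#' @param cpg_ids CpG set.
#' @param groups Quartile labels named by sample ([quartile_groups()]).
#' @return List: `group_means` (Q1..Q4), `trend` one of
#'   `"decreasing"/"increasing"/"neither"`, `test` (a `group_comparison`).
#' @export
infiltration_methylation_trend <- function(meth, cpg_ids, groups) {
  avg <- set_average(meth, cpg_ids)
  groups <- groups[names(avg)]
  gm <- tapply(avg, groups, mean)
  d <- diff(gm)
  trend <- if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing"
    else "neither"
  list(group_means = gm, trend = trend,
       test = kruskal_wallis(avg, groups))
}
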