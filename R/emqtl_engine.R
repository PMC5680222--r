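# Genome-wide expression-methylation correlation screen.
#
# All CpG x gene Pearson correlations are computed in row chunks from masked
# cross-products (pairwise-complete observations), tested against zero with
# the t statistic on n - 2 df, and Bonferroni-thresholded over the number of
# tested pairs.

#' Bonferroni-corrected nominal p-value threshold
#'
#' For a screen of `n_cpg * n_gene` correlation tests at family-wise level
#' `alpha`, the nominal threshold is `alpha / (n_cpg * n_gene)`.
#'
#' @param alpha Family-wise error level.
#' @param n_cpg,n_gene Numbers of CpGs and genes tested.
#' @return The nominal p-value threshold.
#' @export
bonferroni_threshold <- function(alpha, n_cpg, n_gene) {
  stopifnot(alpha > 0, n_cpg > 0, n_gene > 0)
  alpha / (as.numeric(n_cpg) * as.numeric(n_gene))
}

#' Filter CpGs by interquartile range
#'
#' Keeps CpGs whose beta-value IQR across samples exceeds `min_iqr`
#' (strictly), removing invariant probes before the correlation screen.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); missing values are excluded per row. Rows with
#' fewer than 4 non-missing values cannot define quartiles and are dropped
#' with a reason.
#'
#' @param meth CpG-by-sample beta-value matrix.
#' @param min_iqr Strict lower bound on the IQR (default 0.1).
#' @return List with `retained` (CpG ids) and `dropped`
#'   (`data.table(cpg, reason)`).
#' @export
iqr_filter <- function(meth, min_iqr = 0.1) {
  n_ok <- rowSums(!is.na(meth))
  insufficient <- n_ok < 4L
  iqr <- rep(NA_real_, nrow(meth))
  ok <- which(!insufficient)
  if (length(ok)) {
    qs <- apply(meth[ok, , drop = FALSE], 1L, quantile,
                probs = c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
    iqr[ok] <- qs[2L, ] - qs[1L, ]
  }
  keep <- !is.na(iqr) & iqr > min_iqr
  reason <- ifelse(n_ok == 0L, "all_missing",
                   ifelse(insufficient, "too_few_values", "low_iqr"))
  list(retained = rownames(meth)[keep],
       dropped = data.table(cpg = rownames(meth)[!keep],
                            reason = reason[!keep]))
}

#' k-nearest-neighbour imputation of missing matrix values
#'
#' Rows with more than `max_missing_fraction` missing cells are removed. Each
#' remaining missing cell is replaced by the mean, at that column, of the `k`
#' nearest rows by Euclidean distance over shared non-missing columns
#' (distances scaled to the number of shared columns). When fewer than `k`
#' rows have a value at the column, the row mean is used instead.
#'
#' @param m Numeric matrix with rownames.
#' @param k Number of neighbours.
#' @param max_missing_fraction Row-wise missingness ceiling (default 0.5).
#' @return List with `matrix` (imputed), `removed` (row ids) and `fallback`
#'   (`data.table(row, col)` cells imputed by row mean).
#' @export
impute_knn <- function(m, k = 10L, max_missing_fraction = 0.5) {
  stopifnot(k >= 1L)
  frac <- rowMeans(is.na(m))
  removed <- rownames(m)[frac > max_missing_fraction]
  m <- m[frac <= max_missing_fraction, , drop = FALSE]
  out <- m
  miss_rows <- which(rowSums(is.na(m)) > 0L)
  fallback <- list()
  for (i in miss_rows) {
    xi <- m[i, ]
    # scaled Euclidean distance over shared non-missing columns
    d <- vapply(seq_len(nrow(m)), function(j) {
      if (j == i) return(Inf)
      sh <- !is.na(xi) & !is.na(m[j, ])
      if (!any(sh)) return(Inf)
      sqrt(sum((xi[sh] - m[j, sh])^2) / sum(sh) * ncol(m))
    }, numeric(1L))
    ord <- order(d, seq_along(d))  # stable under ties
    for (col in which(is.na(xi))) {
      nb <- ord[!is.na(m[ord, col]) & is.finite(d[ord])]
      if (length(nb) >= k) {
        out[i, col] <- mean(m[nb[seq_len(k)], col])
      } else {
        out[i, col] <- mean(xi, na.rm = TRUE)
        fallback[[length(fallback) + 1L]] <-
          data.table(row = rownames(m)[i], col = colnames(m)[col])
      }
    }
  }
  list(matrix = out, removed = removed,
       fallback = if (length(fallback)) data.table::rbindlist(fallback)
       else data.table(row = character(), col = character()))
}

#' Pearson correlation with a two-sided zero-correlation test
#'
#' Computes the sample Pearson correlation over pairwise-complete
#' observations and its two-sided p-value from `t = r * sqrt(n - 2) /
#' sqrt(1 - r^2)` on `n - 2` degrees of freedom; `|r| = 1` gives `p = 0`.
#' Pairs with fewer than 3 complete observations or zero variance are
#' untestable and return `NA` with a reason rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n` and (if untestable) `reason`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n,
                          reason = "insufficient_n"))
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "zero_variance"))
  }
  r <- cor(x, y)
  list(r = r, p = pearson_p(r, n), n = n)
}

# two-sided p for the t transform of r; |r| >= 1 underflows to 0
pearson_p <- function(r, n) {
  r2 <- pmin(r * r, 1)
  p <- ifelse(r2 >= 1, 0,
              2 * pt(abs(r) * sqrt((n - 2) / pmax(1 - r2, 0)),
                     df = n - 2, lower.tail = FALSE))
  pmin(p, 1)
}

# row-centre by non-missing means; improves conditioning of the raw-moment
# correlation formula without changing any pairwise-complete r
center_rows <- function(m) {
  m - rowMeans(m, na.rm = TRUE)
}

#' All-pairs CpG-gene correlation screen with Bonferroni discovery
#'
#' Tests every CpG row of `meth` against every gene row of `expr` for
#' non-zero Pearson correlation across the shared samples (matched by column
#' name, sorted intersection) and retains pairs with Bonferroni-corrected
#' p-value below `alpha`, where the number of tests `m` is
#' `n_cpg_tested * n_gene_tested`. Computation runs in CpG-row chunks over
#' masked cross-products, so missing cells give pairwise-complete
#' correlations with a per-pair `n`; results are identical for any
#' `chunk_size`.
#'
#' @param meth CpG-by-sample beta matrix (pre-filtered with [iqr_filter()]).
#' @param expr Gene-by-sample expression matrix.
#' @param alpha Family-wise error level (default 0.05).
#' @param chunk_size CpG rows per chunk (default 256).
#' @param keep_all Keep non-significant pairs too (for small fixtures).
#' @return An `emqtl_result` list: `stage`, `m`, `alpha`, `pairs`
#'   (`data.table(cpg, gene, r, n, p, p_bonf, sign)`) and `untestable`
#'   (`data.table(cpg, gene, reason)`).
#' @export
all_pair_emqtl <- function(meth, expr, alpha = 0.05, chunk_size = 256L,
                           keep_all = FALSE) {
  if (chunk_size < 1L) stop("chunk_size must be >= 1")
  shared <- sort(intersect(colnames(meth), colnames(expr)))
  if (length(shared) < 3L) stop("matrices share fewer than 3 sample ids")
  meth <- meth[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]

  untestable <- list()
  drop_rows <- function(m, what) {
    n_ok <- rowSums(!is.na(m))
    v <- apply(m, 1L, function(x) if (sum(!is.na(x)) >= 2L) var(x, na.rm = TRUE) else 0)
    bad <- n_ok < 3L | v == 0
    if (any(bad)) {
      untestable[[length(untestable) + 1L]] <<- data.table(
        cpg = if (what == "cpg") rownames(m)[bad] else "*",
        gene = if (what == "gene") rownames(m)[bad] else "*",
        reason = ifelse(n_ok[bad] < 3L, "insufficient_n", "zero_variance"))
    }
    m[!bad, , drop = FALSE]
  }
  meth <- drop_rows(meth, "cpg")
  expr <- drop_rows(expr, "gene")
  if (nrow(meth) == 0L || nrow(expr) == 0L) stop("no testable rows")
  m_tests <- as.numeric(nrow(meth)) * as.numeric(nrow(expr))
  thr <- alpha / m_tests

  X <- center_rows(meth)
  Y <- center_rows(expr)
  Wy <- !is.na(Y); Y0 <- Y; Y0[!Wy] <- 0
  tWy <- t(Wy); tY0 <- t(Y0); tY2 <- t(Y0 * Y0)
  storage.mode(tWy) <- "double"

  res <- list()
  starts <- seq.int(1L, nrow(X), by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1L, nrow(X))
    Xc <- X[rows, , drop = FALSE]
    Wx <- !is.na(Xc); X0 <- Xc; X0[!Wx] <- 0
    storage.mode(Wx) <- "double"
    n <- Wx %*% tWy
    Sx <- X0 %*% tWy
    Sy <- Wx %*% tY0
    Sxy <- X0 %*% tY0
    Sxx <- (X0 * X0) %*% tWy
    Syy <- Wx %*% tY2
    cv <- Sxy - Sx * Sy / n
    vx <- Sxx - Sx * Sx / n
    vy <- Syy - Sy * Sy / n
    # guard zero variance on the pairwise-complete subset (fp-safe)
    tolx <- 1e-12 * (Sxx + 1e-300)
    toly <- 1e-12 * (Syy + 1e-300)
    bad_n <- n < 3
    bad_v <- (vx <= tolx) | (vy <= toly)
    r <- cv / sqrt(pmax(vx, tolx) * pmax(vy, toly))
    r <- pmin(pmax(r, -1), 1)
    p <- matrix(pearson_p(as.vector(r), as.vector(n)), nrow(r), ncol(r))
    keep <- if (keep_all) !(bad_n | bad_v) else
      (!(bad_n | bad_v)) & (p < thr)
    if (any(bad_n | bad_v)) {
      ij <- which(bad_n | bad_v, arr.ind = TRUE)
      untestable[[length(untestable) + 1L]] <- data.table(
        cpg = rownames(Xc)[ij[, 1L]], gene = rownames(Y)[ij[, 2L]],
        reason = ifelse(bad_n[ij], "insufficient_n", "zero_variance"))
    }
    if (any(keep)) {
      ij <- which(keep, arr.ind = TRUE)
      res[[length(res) + 1L]] <- data.table(
        cpg = rownames(Xc)[ij[, 1L]], gene = rownames(Y)[ij[, 2L]],
        r = r[keep], n = as.integer(n[keep]), p = p[keep])
    }
  }
  pairs <- if (length(res)) data.table::rbindlist(res) else
    data.table(cpg = character(), gene = character(), r = numeric(),
               n = integer(), p = numeric())
  pairs[, `:=`(p_bonf = pmin(1, p * m_tests),
               sign = ifelse(r < 0, "negative", "positive"))]
  data.table::setorder(pairs, cpg, gene)
  structure(list(stage = "discovery", m = m_tests, alpha = alpha,
                 n_cpg_tested = nrow(meth), n_gene_tested = nrow(expr),
                 pairs = pairs,
                 untestable = if (length(untestable))
                   data.table::rbindlist(untestable)
                 else data.table(cpg = character(), gene = character(),
                                 reason = character())),
            class = "emqtl_result")
}

#' @export
print.emqtl_result <- function(x, ...) {
  cat(sprintf("emQTL result set [stage=%s] %d pairs (m=%.6g tests, alpha=%g)\n",
              x$stage, nrow(x$pairs), x$m, x$alpha))
  if (!is.null(x$summary)) {
    s <- x$summary
    cat(sprintf("  input %d | untestable %d | testable %d | validated %d (%.1f%%)\n",
                s$n_input, s$n_untestable, s$n_testable, s$n_validated,
                100 * s$validation_rate))
  }
  invisible(x)
}

#' Re-test discovery pairs in an independent cohort
#'
#' Each significant discovery pair is re-tested in the validation cohort.
#' Pairs whose CpG or gene is absent, has fewer than 3 complete observations
#' or zero variance are untestable; the Bonferroni correction uses the number
#' of testable pairs. A pair validates when its corrected p-value is below
#' `alpha` and (by default) its correlation keeps the discovery sign.
#'
#' @param discovery An `emqtl_result` from [all_pair_emqtl()].
#' @param meth2,expr2 Validation-cohort matrices.
#' @param alpha Family-wise error level.
#' @param require_sign Require sign concordance with discovery
#'   (default `TRUE`).
#' @return An `emqtl_result` with `stage = "validation"` and a `summary` list
#'   (`n_input`, `n_untestable`, `n_testable`, `n_validated`,
#'   `validation_rate`).
#' @export
validate_pairs <- function(discovery, meth2, expr2, alpha = 0.05,
                           require_sign = TRUE) {
  dp <- discovery$pairs
  if (nrow(dp) == 0L) stop("discovery result is empty")
  shared <- sort(intersect(colnames(meth2), colnames(expr2)))
  if (length(shared) < 3L) stop("validation matrices share fewer than 3 samples")
  meth2 <- meth2[, shared, drop = FALSE]
  expr2 <- expr2[, shared, drop = FALSE]

  has_cpg <- dp$cpg %in% rownames(meth2)
  has_gene <- dp$gene %in% rownames(expr2)
  reason <- rep(NA_character_, nrow(dp))
  reason[!has_gene] <- "missing_gene"
  reason[!has_cpg] <- "missing_probe"
  r <- rep(NA_real_, nrow(dp)); p <- r; n <- integer(nrow(dp))
  idx <- which(has_cpg & has_gene)
  if (length(idx)) {
    xm <- meth2[dp$cpg[idx], , drop = FALSE]
    ym <- expr2[dp$gene[idx], , drop = FALSE]
    ok <- !is.na(xm) & !is.na(ym)
    xm[!ok] <- NA; ym[!ok] <- NA
    nn <- rowSums(ok)
    sx <- rowSums(xm, na.rm = TRUE); sy <- rowSums(ym, na.rm = TRUE)
    sxx <- rowSums(xm * xm, na.rm = TRUE); syy <- rowSums(ym * ym, na.rm = TRUE)
    sxy <- rowSums(xm * ym, na.rm = TRUE)
    cv <- sxy - sx * sy / nn
    vx <- sxx - sx^2 / nn; vy <- syy - sy^2 / nn
    tolx <- 1e-12 * (sxx + 1e-300); toly <- 1e-12 * (syy + 1e-300)
    bad <- nn < 3 | vx <= tolx | vy <= toly
    rr <- pmin(pmax(cv / sqrt(pmax(vx, tolx) * pmax(vy, toly)), -1), 1)
    rr[bad] <- NA
    r[idx] <- rr
    n[idx] <- nn
    p[idx] <- pearson_p(rr, nn)
    reason[idx][nn < 3] <- "insufficient_n"
    reason[idx][nn >= 3 & bad] <- "zero_variance"
  }
  testable <- is.na(reason)
  m_tests <- sum(testable)
  if (m_tests == 0L) stop("no testable pairs in validation cohort")
  p_bonf <- pmin(1, p * m_tests)
  sgn <- ifelse(r < 0, "negative", "positive")
  validated <- testable & (p * m_tests < alpha) &
    (!require_sign | sgn == dp$sign)
  pairs <- data.table(cpg = dp$cpg[validated], gene = dp$gene[validated],
                      r = r[validated], n = n[validated], p = p[validated],
                      p_bonf = p_bonf[validated], sign = sgn[validated])
  data.table::setorder(pairs, cpg, gene)
  summary <- list(n_input = nrow(dp), n_untestable = sum(!testable),
                  n_testable = m_tests, n_validated = sum(validated),
                  validation_rate = sum(validated) / m_tests)
  structure(list(stage = "validation", m = m_tests, alpha = alpha,
                 pairs = pairs,
                 untestable = data.table(cpg = dp$cpg[!testable],
                                         gene = dp$gene[!testable],
                                         reason = reason[!testable]),
                 summary = summary),
            class = "emqtl_result")
}

#' Fraction of reference emQTL pairs rediscovered in another screen
#'
#' @param reference,rediscovered `emqtl_result` objects; pair identity is the
#'   (cpg, gene) key, correlation magnitudes are ignored.
#' @return Fraction in `[0, 1]`.
#' @export
rediscovery_rate <- function(reference, rediscovered) {
  ref <- reference$pairs
  if (nrow(ref) == 0L) stop("reference set is empty")
  key <- function(d) paste(d$cpg, d$gene, sep = "\r")
  mean(key(ref) %in% key(rediscovered$pairs))
}

#' Serialize / read an emQTL pair table
#'
#' Pairs are written as (optionally gzipped) TSV with columns
#' `cpg, gene, r, n, p, p_bonf, sign, stage`.
#'
#' @param result An `emqtl_result`.
#' @param path Output path (`.gz` suffix gzips).
#' @export
write_emqtl_pairs <- function(result, path) {
  d <- data.table::copy(result$pairs)
  d[, stage := result$stage]
  fwrite(d, path, sep = "\t",
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_emqtl_pairs
#' @param m Number of tests the stage used (stored alongside when reloading).
#' @param alpha Significance level.
#' @export
read_emqtl_pairs <- function(path, m = NA_real_, alpha = 0.05) {
  d <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    fread(text = readLines(con), sep = "\t")
  } else fread(path, sep = "\t")
  stage <- if ("stage" %in% names(d) && nrow(d)) d$stage[1L] else "discovery"
  d[, stage := NULL]
  structure(list(stage = stage, m = m, alpha = alpha, pairs = d,
                 untestable = data.table(cpg = character(), gene = character(),
                                         reason = character())),
            class = "emqtl_result")
}
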