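# Enrichment of CpG sets and CpG-gene pairs against genomic annotations:
# chromatin states, TF ChIP-seq peaks (optionally +/- 200 bp windows),
# permutation nulls, chromatin loops, cis (10 kb) pairing, gene sets.

#' Upper-tail hypergeometric enrichment of a query set
#'
#' With `N` background ids of which `K` are annotated, and a query of `n` ids
#' containing `k` annotated ones, computes `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` and the enrichment ratio
#' `(k/n) / (K/N)` (observed hit fraction over the background hit fraction).
#'
#' @param query,annotated,background Character id vectors; `query` and
#'   `annotated` must be subsets of `background`.
#' @param category Label stored on the result.
#' @return A one-row `data.table`: `category, n_query, n_query_hits,
#'   n_background, n_background_hits, ratio, p`.
#' @export
hypergeom_enrichment <- function(query, annotated, background,
                                 category = "annotation") {
  query <- unique(query); annotated <- unique(annotated)
  background <- unique(background)
  if (length(query) == 0L || length(background) == 0L) {
    stop("query and background must be non-empty")
  }
  if (!all(query %in% background)) stop("query must be a subset of background")
  if (!all(annotated %in% background)) {
    stop("annotated set must be a subset of background")
  }
  N <- length(background); K <- length(annotated); n <- length(query)
  k <- length(intersect(query, annotated))
  if (K == 0L) {
    return(data.table(category = category, n_query = n, n_query_hits = 0L,
                      n_background = N, n_background_hits = 0L,
                      ratio = 0, p = 1))
  }
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.table(category = category, n_query = n, n_query_hits = k,
             n_background = N, n_background_hits = K,
             ratio = (k / n) / (K / N), p = p)
}

# map each CpG id to the chromatin state containing its base
assign_states <- function(cpg_ids, cpg_map, segmentation) {
  m <- cpg_map[match(cpg_ids, cpg_map$cpg)]
  if (anyNA(m$chrom)) stop("unmappable CpG: ", cpg_ids[which(is.na(m$chrom))[1L]])
  out <- rep("unannotated", length(cpg_ids))
  for (ch in unique(m$chrom)) {
    ti <- which(segmentation$chrom == ch)
    qi <- which(m$chrom == ch)
    if (length(ti) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(m$pos[qi] + 1L, m$pos[qi] + 1L),
      IRanges::IRanges(segmentation$start[ti] + 1L, segmentation$end[ti]),
      select = "first")
    found <- !is.na(hits)
    out[qi[found]] <- segmentation$label[ti[hits[found]]]
  }
  out
}

state_collapse_map <- c(
  "Enhancer" = "Enhancer", "Enhancer+CTCF" = "Enhancer",
  "Promoter" = "Promoter", "Promoter+CTCF" = "Promoter",
  "Poised Promoter" = "Promoter")

#' Chromatin-state enrichment profile of a CpG set
#'
#' Each CpG is assigned the single segmentation state containing its base
#' (segmentations tile the genome, so states are exclusive; CpGs outside all
#' segments fall in a sentinel `unannotated` state). One hypergeometric test
#' per state against the background universe. With `collapse = TRUE` the
#' CTCF-flavoured enhancer state merges into `Enhancer` and the promoter
#' variants (including poised) into `Promoter`.
#'
#' @param cpg_ids Query CpG ids.
#' @param cpg_map `data.table(cpg, chrom, pos)` mapping probes to positions.
#' @param segmentation Interval track of chromatin states (label = state).
#' @param background Background CpG ids (e.g. the array universe).
#' @param collapse Merge enhancer/promoter state families (default `TRUE`).
#' @return `data.table` with one enrichment row per state.
#' @export
chromhmm_profile <- function(cpg_ids, cpg_map, segmentation, background,
                             collapse = TRUE) {
  if (!all(cpg_ids %in% background)) stop("query must be a subset of background")
  st <- assign_states(background, cpg_map, segmentation)
  if (collapse) {
    mapped <- state_collapse_map[st]
    st <- ifelse(is.na(mapped), st, mapped)
  }
  states <- sort(unique(st))
  res <- lapply(states, function(s) {
    hypergeom_enrichment(cpg_ids, background[st == s], background,
                         category = s)
  })
  data.table::rbindlist(res)
}

# hit indicator: window around each CpG overlaps >= 1 interval of the track
peak_hits <- function(cpg_ids, cpg_map, track, half_width = 0) {
  m <- cpg_map[match(cpg_ids, cpg_map$cpg)]
  if (anyNA(m$chrom)) stop("unmappable CpG: ", cpg_ids[which(is.na(m$chrom))[1L]])
  w <- window_around(m$pos, half_width)
  overlap_any(track, m$chrom, w$start, w$end)
}

#' TF-peak enrichment of a CpG set
#'
#' A CpG is a hit when the window of `half_width` bp around its base
#' ([window_around()]) overlaps at least one peak; `half_width = 0` tests the
#' CpG base itself. Hypergeometric test against the background universe.
#'
#' @param cpg_ids,cpg_map,background As in [chromhmm_profile()].
#' @param track Peak interval track (or a list of tracks, whose union is
#'   used).
#' @param half_width Window half-width in bp (0 or 200 in practice).
#' @param category Label for the result row.
#' @return A one-row enrichment `data.table`.
#' @export
peak_enrichment <- function(cpg_ids, cpg_map, track, background,
                            half_width = 0, category = "peaks") {
  if (is.list(track) && !is.data.frame(track)) {
    track <- data.table::rbindlist(track)
  }
  if (!all(cpg_ids %in% background)) stop("query must be a subset of background")
  hits <- peak_hits(background, cpg_map, track, half_width)
  hypergeom_enrichment(cpg_ids, background[hits], background,
                       category = category)
}

#' Permutation test of CpG-set overlap with a peak-track union
#'
#' Counts how many query CpGs fall in the union of the supplied tracks, then
#' repeatedly samples `|query|` CpGs without replacement from the background
#' and recounts. The p-value uses the add-one correction
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`, so an observation exceeding
#' every permutation reports `p = 1/(n_perm + 1)` (the "p < 0.001" situation
#' at 1000 permutations).
#'
#' @param cpg_ids Query CpG ids.
#' @param cpg_map Probe position map.
#' @param tracks A track or list of tracks; their union defines a hit.
#' @param background Background CpG ids to resample from.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param half_width Window half-width for hits (default 0).
#' @return List of class `permutation_result`: `observed`, `perm_counts`,
#'   `n_perm`, `p`, `seed`.
#' @export
permutation_enrichment <- function(cpg_ids, cpg_map, tracks, background,
                                   n_perm = 1000L, seed = 1L,
                                   half_width = 0) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(background) < length(cpg_ids)) {
    stop("background smaller than query")
  }
  if (is.list(tracks) && !is.data.frame(tracks)) {
    tracks <- data.table::rbindlist(tracks)
  }
  hit <- setNames(peak_hits(background, cpg_map, tracks, half_width),
                  background)
  observed <- sum(hit[cpg_ids])
  nq <- length(cpg_ids)
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(hit[sample.int(length(hit), nq)]),
           integer(1L))
  })
  p <- (1 + sum(perm_counts >= observed)) / (n_perm + 1)
  structure(list(observed = observed, perm_counts = perm_counts,
                 n_perm = n_perm, p = p, seed = seed),
            class = "permutation_result")
}

# loop support indicator for CpG-gene pairs: the CpG base sits in one anchor
# and the gene TSS in the other anchor of the same loop (either orientation)
loop_supported <- function(pairs, loops, cpg_map, gene_models) {
  cm <- cpg_map[match(pairs$cpg, cpg_map$cpg)]
  gm <- gene_models[match(pairs$gene, gene_models$gene)]
  ok <- !is.na(cm$chrom) & !is.na(gm$chrom)
  anchor_hits <- function(chrom, pos, a_chrom, a_start, a_end) {
    # list of loop indices whose anchor contains each point
    res <- vector("list", length(chrom))
    for (ch in unique(chrom)) {
      li <- which(a_chrom == ch)
      qi <- which(chrom == ch)
      if (!length(li) || !length(qi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(pos[qi] + 1L, pos[qi] + 1L),
        IRanges::IRanges(a_start[li] + 1L, a_end[li]))
      sp <- split(li[S4Vectors::subjectHits(hits)],
                  factor(S4Vectors::queryHits(hits), levels = seq_along(qi)))
      for (j in seq_along(qi)) res[[qi[j]]] <- sp[[j]]
    }
    res
  }
  cA <- anchor_hits(cm$chrom, cm$pos, loops$chromA, loops$startA, loops$endA)
  cB <- anchor_hits(cm$chrom, cm$pos, loops$chromB, loops$startB, loops$endB)
  gA <- anchor_hits(gm$chrom, gm$tss, loops$chromA, loops$startA, loops$endA)
  gB <- anchor_hits(gm$chrom, gm$tss, loops$chromB, loops$startB, loops$endB)
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    if (!ok[i]) return(NA)
    length(intersect(cA[[i]], gB[[i]])) > 0L ||
      length(intersect(cB[[i]], gA[[i]])) > 0L
  }, logical(1L))
  hit
}

#' Loop (chromatin-interaction) enrichment of emQTL pairs
#'
#' A CpG-gene pair is loop-supported when some loop has the CpG base in one
#' anchor and the gene's TSS in the other (orientation-symmetric).
#' Enrichment is hypergeometric over an explicit background pair universe
#' (by default the pair set the query was drawn from, e.g. all validated
#' emQTL pairs).
#'
#' @param pairs `data.table(cpg, gene)` query pairs (subset of `background`).
#' @param loops Loop table from [read_loops()].
#' @param cpg_map,gene_models Position maps.
#' @param background Background `data.table(cpg, gene)` pair universe.
#' @return A one-row enrichment `data.table` plus attribute `hits` (logical
#'   per query pair).
#' @export
loop_enrichment <- function(pairs, loops, cpg_map, gene_models, background) {
  bg_key <- paste(background$cpg, background$gene, sep = "\r")
  q_key <- paste(pairs$cpg, pairs$gene, sep = "\r")
  if (!all(q_key %in% bg_key)) stop("query pairs must be in the background")
  hit <- loop_supported(background, loops, cpg_map, gene_models)
  usable <- !is.na(hit)
  bg_ids <- bg_key[usable]
  res <- hypergeom_enrichment(q_key[q_key %in% bg_ids],
                              bg_ids[hit[usable]], bg_ids,
                              category = "loops")
  attr(res, "hits") <- setNames(hit[match(q_key, bg_key)], q_key)
  res
}

#' Flag cis (local) CpG-gene pairs and the locally paired gene fraction
#'
#' A pair is local when CpG and TSS share a chromosome and are at most
#' `max_dist` bp apart. The reported fraction is the share of distinct genes
#' in `pairs` having at least one local CpG among their pairs.
#'
#' @param pairs `data.table(cpg, gene)` (e.g. a clique's validated pairs).
#' @param cpg_map,gene_models Position maps.
#' @param max_dist Maximum CpG-TSS distance in bp (default 10000).
#' @return List with `pairs` (input plus `distance` and `local` columns) and
#'   `local_gene_fraction`.
#' @export
local_pairs <- function(pairs, cpg_map, gene_models, max_dist = 10000) {
  cm <- cpg_map[match(pairs$cpg, cpg_map$cpg)]
  gm <- gene_models[match(pairs$gene, gene_models$gene)]
  same <- cm$chrom == gm$chrom
  distance <- ifelse(same, abs(cm$pos - gm$tss), NA_real_)
  local <- !is.na(distance) & distance <= max_dist
  out <- data.table(cpg = pairs$cpg, gene = pairs$gene,
                    distance = distance, local = local)
  frac <- if (nrow(out)) {
    length(unique(out$gene[out$local])) / length(unique(out$gene))
  } else NA_real_
  list(pairs = out, local_gene_fraction = frac)
}

#' Gene-set enrichment of a gene list by hypergeometric test
#'
#' One upper-tail hypergeometric test per collection set, using the supplied
#' background gene universe; results are ranked by p-value.
#'
#' @param genes Query gene ids.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param background Background gene universe.
#' @return `data.table` of enrichment rows, ordered by increasing `p`.
#' @export
gene_set_enrichment <- function(genes, collection, background) {
  if (length(collection) == 0L) stop("empty collection")
  if (!any(unlist(collection) %in% background)) {
    stop("background shares no genes with the collection")
  }
  res <- data.table::rbindlist(lapply(names(collection), function(nm) {
    hypergeom_enrichment(genes, intersect(collection[[nm]], background),
                         background, category = nm)
  }))
  data.table::setorder(res, p, category)
  res
}

#' Overlap of a gene set with named target lists
#'
#' Fraction of the gene set contained in each target list and in their
#' union (e.g. the share of clique genes that are ERα/FOXA1/GATA3 targets).
#'
#' @param genes Query gene ids.
#' @param target_lists Named list of gene id vectors.
#' @return List with `per_list` (named fractions) and `union_fraction`.
#' @export
target_overlap <- function(genes, target_lists) {
  stopifnot(length(target_lists) > 0L, all(lengths(target_lists) > 0L))
  genes <- unique(genes)
  per <- vapply(target_lists, function(l) mean(genes %in% l), numeric(1L))
  uni <- mean(genes %in% unique(unlist(target_lists)))
  list(per_list = per, union_fraction = uni)
}

#' Differentially methylated CpGs by median difference
#'
#' A CpG passes when the absolute difference of group medians is at least
#' `min_diff` and the two-sided rank-sum (Mann-Whitney) p-value is below
#' `alpha`. CpGs with fewer than `min_n` values in either group are skipped.
#'
#' @param meth CpG-by-sample beta matrix.
#' @param group_a,group_b Sample id vectors.
#' @param min_diff Minimum absolute median difference (default 0.1).
#' @param alpha Nominal p-value cutoff (default 0.05).
#' @param min_n Minimum per-group sample count (default 3).
#' @return `data.table(cpg, median_a, median_b, median_diff, p, pass)`;
#'   skipped CpGs carry `NA` p.
#' @export
differential_median_cpgs <- function(meth, group_a, group_b, min_diff = 0.1,
                                     alpha = 0.05, min_n = 3L) {
  a <- meth[, intersect(group_a, colnames(meth)), drop = FALSE]
  b <- meth[, intersect(group_b, colnames(meth)), drop = FALSE]
  if (ncol(a) < min_n || ncol(b) < min_n) stop("both groups need >= min_n samples")
  res <- lapply(seq_len(nrow(meth)), function(i) {
    xa <- a[i, ][!is.na(a[i, ])]
    xb <- b[i, ][!is.na(b[i, ])]
    if (length(xa) < min_n || length(xb) < min_n) {
      return(data.table(cpg = rownames(meth)[i], median_a = NA_real_,
                        median_b = NA_real_, median_diff = NA_real_,
                        p = NA_real_, pass = FALSE))
    }
    md <- median(xa) - median(xb)
    p <- if (var(c(xa, xb)) == 0) 1 else
      suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
    data.table(cpg = rownames(meth)[i], median_a = median(xa),
               median_b = median(xb), median_diff = md, p = p,
               pass = abs(md) >= min_diff && !is.na(p) && p < alpha)
  })
  data.table::rbindlist(res)
}
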