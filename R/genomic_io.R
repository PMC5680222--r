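#' @importFrom data.table data.table fread fwrite setDT as.data.table :=
#' @importFrom stats cor cutree hclust as.dist dist median quantile phyper
#'   pt setNames wilcox.test kruskal.test rbeta rnorm runif rbinom plogis
#'   qlogis cor.test sd var
#' @importFrom utils head
NULL

# All genomic coordinates are 0-based half-open (BED convention) internally.
# Tracks are data.tables with columns chrom, start, end, label.

#' Read a BED / narrowPeak interval track
#'
#' Parses a BED 3+ or ENCODE narrowPeak file into an interval table using
#' 0-based half-open coordinates. Browser/track/comment lines are skipped.
#' Column 4, when present, becomes the interval label.
#'
#' @param path Path to a (possibly gzipped) tab-separated file.
#' @param format `"bed"` or `"narrowpeak"`; both use columns 1-3 for
#'   coordinates and column 4 for the label, the distinction is documentary.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_interval_track <- function(path, format = c("bed", "narrowpeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L)) {
    stop("line ", idx[which(nfield < 3L)[1L]], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", idx[bad[1L]], ": non-integer coordinate")
  bad <- which(end <= start | start < 0L)
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": invalid interval (need 0 <= start < end)")
  }
  label <- ifelse(nfield >= 4L,
                  vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                         character(1L)),
                  "")
  data.table(chrom = chrom, start = start, end = end, label = label)
}

#' Read chromatin-interaction loops
#'
#' Reads paired-anchor loops from a BEDPE-style file
#' (`chromA startA endA chromB startB endB [name]`). Loop ids default to
#' `loop_<row>` when no name column is present.
#'
#' @param path Path to a tab-separated file with at least 6 columns.
#' @return A `data.table` with columns `loop_id`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`.
#' @export
read_loops <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- data.table(loop_id = character(), chromA = character(),
                      startA = integer(), endA = integer(),
                      chromB = character(), startB = integer(),
                      endB = integer())
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 6L)) {
    stop("line ", idx[which(nfield < 6L)[1L]], ": fewer than 6 columns")
  }
  col <- function(j) vapply(fields, `[[`, character(1L), j)
  out <- data.table(
    loop_id = if (all(nfield >= 7L)) col(7L) else paste0("loop_", seq_along(idx)),
    chromA = col(1L),
    startA = suppressWarnings(as.integer(col(2L))),
    endA = suppressWarnings(as.integer(col(3L))),
    chromB = col(4L),
    startB = suppressWarnings(as.integer(col(5L))),
    endB = suppressWarnings(as.integer(col(6L))))
  bad <- which(is.na(out$startA) | is.na(out$endA) | is.na(out$startB) |
                 is.na(out$endB))
  if (length(bad)) stop("line ", idx[bad[1L]], ": non-integer coordinate")
  bad <- which(out$endA <= out$startA | out$endB <= out$startB |
                 out$startA < 0L | out$startB < 0L)
  if (length(bad)) stop("line ", idx[bad[1L]], ": invalid anchor interval")
  if (anyDuplicated(out$loop_id)) stop("duplicate loop id")
  out[]
}

#' Intervals overlapping a query
#'
#' Returns the rows of `track` whose interval overlaps the half-open query
#' interval on the same chromosome. Strand, if any, is ignored.
#'
#' @param track Interval table from [read_interval_track()].
#' @param chrom,start,end Query interval (0-based half-open).
#' @return The overlapping subset of `track`, in track order.
#' @export
overlapping <- function(track, chrom, start, end) {
  stopifnot(end > start, start >= 0)
  hit <- track$chrom == chrom & track$start < end & track$end > start
  track[hit]
}

# Vectorised overlap indicator: for each query point/interval, TRUE iff it
# overlaps >= 1 track interval. Queries given as parallel vectors.
overlap_any <- function(track, qchrom, qstart, qend) {
  out <- logical(length(qchrom))
  if (nrow(track) == 0L || length(qchrom) == 0L) return(out)
  for (ch in unique(qchrom)) {
    ti <- which(track$chrom == ch)
    qi <- which(qchrom == ch)
    if (length(ti) == 0L || length(qi) == 0L) next
    sub <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    qry <- IRanges::IRanges(start = qstart[qi] + 1L, end = qend[qi])
    out[qi] <- IRanges::overlapsAny(qry, sub)
  }
  out
}

#' Symmetric window around a genomic position
#'
#' Builds the half-open interval covering every base within `half_width` bp of
#' a single-base position, clipped at the chromosome start:
#' `[max(0, position - half_width), position + half_width + 1)`.
#'
#' @param position 0-based base position (vectorised).
#' @param half_width Window half-width in bp, `>= 0`.
#' @return A list with `start` and `end` vectors.
#' @export
window_around <- function(position, half_width) {
  if (any(half_width < 0)) stop("half_width must be >= 0")
  if (any(position < 0)) stop("position must be >= 0")
  list(start = pmax(0, position - half_width),
       end = position + half_width + 1)
}

#' Read / write a feature-by-sample numeric matrix
#'
#' Tab-separated text with sample ids in the first row and feature ids in the
#' first column. Empty cells are missing values. The write/read round trip is
#' lossless to 12 significant digits.
#'
#' @param path File path (gzip accepted on read; a `.gz` suffix gzips on
#'   write).
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_numeric_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty matrix file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples)) stop("duplicate column id in ", path)
  body <- fields[-1L]
  if (length(body)) {
    # a trailing empty cell is dropped by strsplit; pad before checking
    body <- lapply(body, function(f) {
      if (length(f) == length(samples)) c(f, "") else f
    })
    if (any(lengths(body) != length(samples) + 1L)) {
      stop("ragged row in ", path)
    }
  }
  feats <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(feats)) stop("duplicate row id in ", path)
  vals <- vapply(body, function(f) {
    v <- f[-1L]
    v[v == ""] <- NA_character_
    as.numeric(v)
  }, numeric(length(samples)))
  m <- if (length(samples) == 1L) matrix(vals, nrow = length(feats)) else t(vals)
  if (length(feats) == 0L) m <- matrix(numeric(), 0L, length(samples))
  dimnames(m) <- list(feats, samples)
  m
}

#' @rdname read_numeric_matrix
#' @param m Numeric matrix with row and column names.
#' @export
write_numeric_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) {
    s <- sprintf("%.15g", v)
    s[is.na(v)] <- ""
    s
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1L))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `set_name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @param uppercase Upper-case gene symbols on read (default `TRUE`) so all
#'   gene-id comparisons share one namespace.
#' @return Named list of character vectors (one per set, order preserved).
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("line ", which(lengths(fields) < 3L)[1L],
         ": GMT record needs name, description and >= 1 gene")
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (uppercase) g <- toupper(g)
    g
  })
  setNames(sets, nm)
}

#' Write a BED-like track or BEDPE-like loop table
#'
#' @param track Interval table (`chrom,start,end,label`) or loop table
#'   (`loop_id,chromA,...`).
#' @param path Output path.
#' @keywords internal
write_interval_track <- function(track, path) {
  fwrite(track[, c("chrom", "start", "end", "label")], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

write_loops <- function(loops, path) {
  fwrite(loops[, c("chromA", "startA", "endA", "chromB", "startB", "endB",
                   "loop_id")], path, sep = "\t", col.names = FALSE)
  invisible(path)
}
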