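#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
NULL

## Coordinates throughout are BED convention: 0-based, half-open [start, end).
## GRanges is 1-based closed, so conversion is start+1 on the way in and
## start-1 on the way out; interval widths and gap widths are unchanged.

#' Construct a set of methylated regions for one sample
#'
#' A `region_set` holds the detected methylated regions (e.g. enrichment-seq
#' peaks) of one biological sample. Intervals are stored 0-based half-open,
#' and are sorted and merged at construction so that "number of regions" is
#' well defined: overlapping or book-ended input records collapse into one
#' region.
#'
#' @param chrom Character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end` (in which case `start`/`end` are ignored).
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param sample_id,cell_type Optional labels carried along for bookkeeping.
#' @return An object of class `region_set` with fields `sample_id`,
#'   `cell_type` and `intervals` (a data frame `chrom`, `start`, `end`).
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(100L, 150L), c(200L, 300L))
#' n_regions(rs) # 1: the two records overlap and merge
#' @export
region_set <- function(chrom, start = NULL, end = NULL,
                       sample_id = NA_character_, cell_type = NA_character_) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom),
                     start = as.integer(start), end = as.integer(end),
                     stringsAsFactors = FALSE)
  }
  validate_intervals(df)
  out <- structure(
    list(sample_id = as.character(sample_id),
         cell_type = as.character(cell_type),
         intervals = merge_intervals(df)),
    class = "region_set")
  out
}

validate_intervals <- function(df, where = "intervals") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("invalid interval in %s (row %d): %s:%s-%s (need 0 <= start < end)",
                 where, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  }
  invisible(df)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions (sample_id=%s, cell_type=%s)\n",
              n_regions(x), x$sample_id, x$cell_type))
  if (n_regions(x) > 0) {
    print(utils::head(x$intervals, 6), row.names = FALSE)
    if (n_regions(x) > 6) cat(sprintf("... and %d more\n", n_regions(x) - 6))
  }
  invisible(x)
}

#' Number of regions in a region set
#' @param x A `region_set`, `consensus_set`, or interval data frame.
#' @return Integer count of (merged) regions.
#' @export
n_regions <- function(x) {
  nrow(intervals_of(x))
}

#' @export
as.data.frame.region_set <- function(x, ...) x$intervals

## Accept region_set, consensus_set, or bare chrom/start/end data frame.
intervals_of <- function(x) {
  if (inherits(x, "region_set")) return(x$intervals)
  if (inherits(x, "consensus_set")) return(x$regions)
  if (is.data.frame(x)) return(x)
  stop("expected a region_set, consensus_set, or interval data frame",
       call. = FALSE)
}

as_granges <- function(x) {
  df <- intervals_of(x)
  if (nrow(df) == 0) return(GRanges())
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

granges_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   stringsAsFactors = FALSE)
  # lexicographic (chrom, start) order, independent of seqlevel order
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Put two GRanges on a common seqlevel universe so set operations do not warn.
harmonize <- function(a, b) {
  lev <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lev
  seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Merge (flatten) genomic intervals
#'
#' Sorts intervals and unions any pair separated by at most `gap` base pairs,
#' so the output is sorted and pairwise separated by more than `gap`. With the
#' default `gap = 0`, overlapping and book-ended intervals are joined and the
#' set of covered bases is preserved exactly.
#'
#' @param x Interval data frame (`chrom`, `start`, `end`), `region_set`, or
#'   `consensus_set`; 0-based half-open.
#' @param gap Non-negative integer: intervals whose separation is `<= gap` bp
#'   are joined.
#' @return A sorted interval data frame.
#' @export
merge_intervals <- function(x, gap = 0L) {
  stopifnot(length(gap) == 1, gap >= 0)
  df <- intervals_of(x)
  validate_intervals(df)
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(df)
  o <- order(df$chrom, df$start, df$end)
  ch <- as.character(df$chrom[o])
  s <- as.integer(df$start[o])
  e <- as.integer(df$end[o])
  # scanline: running max end within chromosome; a row starts a new merged
  # interval when it is on a new chromosome or separated by more than `gap`
  cm <- as.integer(stats::ave(e, ch, FUN = cummax))
  new_grp <- c(TRUE, ch[-1] != ch[-n] | s[-1] > cm[-n] + gap)
  last_of_grp <- c(new_grp[-1], TRUE)
  data.frame(chrom = ch[new_grp], start = s[new_grp], end = cm[last_of_grp],
             stringsAsFactors = FALSE)
}

## logical: does each query row share >= min_overlap bases with at least one
## subject row? (IRanges interval tree per chromosome; coordinates half-open)
overlaps_any <- function(qdf, sdf, min_overlap = 1L) {
  keep <- logical(nrow(qdf))
  for (ch in intersect(unique(qdf$chrom), unique(sdf$chrom))) {
    qi <- which(qdf$chrom == ch)
    si <- sdf$chrom == ch
    keep[qi] <- IRanges::countOverlaps(
      IRanges(qdf$start[qi] + 1L, qdf$end[qi]),
      IRanges(sdf$start[si] + 1L, sdf$end[si]),
      minoverlap = as.integer(min_overlap)) > 0
  }
  keep
}

#' Base-pair intersection of two region sets
#'
#' Returns the merged intervals covering exactly the bases covered by both
#' inputs — the realization used for "overlapping methylated regions" when
#' collapsing replicates to a consensus.
#'
#' @param a,b `region_set`s, `consensus_set`s, or interval data frames.
#' @return A sorted interval data frame of the shared bases.
#' @export
intersect_bases <- function(a, b) {
  am <- merge_intervals(a)
  bm <- merge_intervals(b)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  parts <- lapply(intersect(unique(am$chrom), unique(bm$chrom)), function(ch) {
    ai <- am[am$chrom == ch, ]
    bi <- bm[bm$chrom == ch, ]
    h <- IRanges::findOverlaps(IRanges(ai$start + 1L, ai$end),
                               IRanges(bi$start + 1L, bi$end))
    if (length(h) == 0) return(NULL)
    qi <- S4Vectors::queryHits(h)
    si <- S4Vectors::subjectHits(h)
    # clip each overlapping pair; both sides are merged, so clips of one
    # chromosome are already disjoint
    data.frame(chrom = ch,
               start = pmax(ai$start[qi], bi$start[si]),
               end = pmin(ai$end[qi], bi$end[si]),
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) return(empty)
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence-overlap filter (intersectBed -u semantics)
#'
#' Keeps the query regions that overlap at least one subject region by at
#' least `min_overlap` base pairs; kept query coordinates are returned
#' unmodified. This is the presence test used when asking whether a consensus
#' region "was also detected" in another sample.
#'
#' @param query,subject `region_set`s, `consensus_set`s, or interval data
#'   frames.
#' @param min_overlap Positive integer minimum shared base pairs (default 1).
#' @return An object of the same flavor as `query` (a `region_set` keeps its
#'   labels) containing the kept intervals.
#' @export
overlap_filter <- function(query, subject, min_overlap = 1L) {
  stopifnot(length(min_overlap) == 1, min_overlap >= 1)
  qdf <- intervals_of(query)
  keep <- overlaps_any(qdf, intervals_of(subject), min_overlap)
  kept <- qdf[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (inherits(query, "region_set")) {
    out <- query
    out$intervals <- kept
    return(out)
  }
  kept
}

#' Read a BED3+ file into a region set
#'
#' Reads tab-separated BED (0-based half-open); `#`, `track` and `browser`
#' lines are skipped and columns beyond the third are ignored. Records are
#' merged at construction. An empty file yields an empty `region_set`.
#'
#' @param path Path to a BED file.
#' @param sample_id,cell_type Optional labels (default: file base name / NA).
#' @return A `region_set`.
#' @export
read_bed <- function(path, sample_id = NULL, cell_type = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bed$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(region_set(data.frame(chrom = character(), start = integer(),
                                 end = integer()),
                      sample_id = sample_id, cell_type = cell_type))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop(sprintf("%s: line %d has %d field(s); BED needs at least 3",
                 path, idx[bad], nf[bad]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s: malformed coordinates at line %d: %s",
                 path, idx[bad[1]], lines[idx[bad[1]]]), call. = FALSE)
  }
  region_set(data.frame(chrom = chrom, start = start, end = end,
                        stringsAsFactors = FALSE),
             sample_id = sample_id, cell_type = cell_type)
}

#' Write intervals as sorted BED3
#'
#' @param x A `region_set`, `consensus_set`, or interval data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  df <- merge_intervals(x) # sorted; merging is a no-op for constructed sets
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0) {
    writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), con)
  }
  invisible(path)
}

#' Total bases covered by a set of intervals
#' @param x A `region_set`, `consensus_set`, or interval data frame.
#' @return Integer number of covered base pairs.
#' @export
covered_bases <- function(x) {
  df <- merge_intervals(x)
  sum(df$end - df$start)
}
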