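#' Build the replicate-consensus region set of one cell type
#'
#' The consensus of a cell type is the base-pair intersection of the
#' methylated regions across all of its biological replicates: a base belongs
#' to the consensus iff it is covered in every replicate. With a single
#' replicate the consensus is that replicate's regions.
#'
#' @param samples List of `region_set`s, all carrying the same `cell_type`
#'   label (an `NA` label is tolerated when `cell_type` is given explicitly).
#' @param cell_type Optional label; defaults to the samples' shared label.
#' @return A `consensus_set`: fields `cell_type`, `regions` (merged interval
#'   data frame) and `n_replicates`.
#' @export
build_consensus <- function(samples, cell_type = NULL) {
  if (!is.list(samples) || length(samples) == 0) {
    stop("need at least 1 sample", call. = FALSE)
  }
  labels <- unique(vapply(samples, function(s) s$cell_type, character(1)))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1) {
    stop("samples mix cell types: ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cell_type)) {
    cell_type <- if (length(labels)) labels else NA_character_
  }
  regions <- intervals_of(samples[[1]])
  for (s in samples[-1]) regions <- intersect_bases(regions, s)
  structure(list(cell_type = cell_type,
                 regions = merge_intervals(regions),
                 n_replicates = length(samples)),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d regions across %d replicates (cell_type=%s)\n",
              nrow(x$regions), x$n_replicates, x$cell_type))
  invisible(x)
}

#' Label consensus regions against the other cell type's samples
#'
#' Each consensus region is tested for presence (overlap of at least
#' `min_overlap` bp with at least one region) in each sample of the other
#' cell type, one by one. A region detected in none of them is a DMR
#' (differentially methylated region); detected in all of them, a CMR
#' (commonly methylated region); otherwise PARTIAL.
#'
#' @param consensus A `consensus_set`.
#' @param other_samples List of `region_set`s of the other cell type (>= 1).
#' @param min_overlap Minimum shared base pairs for presence (default 1).
#' @return A data frame: `chrom`, `start`, `end`, `n_other_supporting`,
#'   `label` in `{DMR, CMR, PARTIAL}`.
#' @export
classify_against <- function(consensus, other_samples, min_overlap = 1L) {
  stopifnot(inherits(consensus, "consensus_set"))
  if (!is.list(other_samples) || length(other_samples) == 0) {
    stop("need at least 1 sample of the other cell type", call. = FALSE)
  }
  regions <- consensus$regions
  n_other <- length(other_samples)
  support <- integer(nrow(regions))
  if (nrow(regions) > 0) {
    for (s in other_samples) {
      support <- support +
        as.integer(overlaps_any(regions, intervals_of(s), min_overlap))
    }
  }
  label <- ifelse(support == 0, "DMR",
                  ifelse(support == n_other, "CMR", "PARTIAL"))
  out <- regions
  out$n_other_supporting <- support
  out$label <- label
  out
}

#' Compare the methylated regions of two cell types
#'
#' The pipeline's core computation: build each cell type's replicate
#' consensus, label every consensus region as DMR / CMR / PARTIAL against the
#' other type's samples, unify the two CMR lists by coordinate union (a
#' region common to both types is counted once), and summarize the DMR/CMR
#' partition as percentages. PARTIAL regions (present in some but not all
#' samples of the other type) are kept in the result but excluded from
#' `n_total` and the percentages, so that DMR-A + DMR-B + CMR = 100%.
#'
#' @param samples_a,samples_b Lists of `region_set`s, one list per cell type.
#' @param min_overlap Minimum shared base pairs for presence (default 1).
#' @param direction `"both"` (default) classifies both consensuses;
#'   `"a_only"` classifies only cell type A's consensus (the one-directional
#'   reading), leaving the B-specific DMR list empty.
#' @param cell_type_a,cell_type_b Optional display labels.
#' @return A `dmr_comparison` object with interval data frames `dmr_a`,
#'   `dmr_b`, `cmr`, `partial_a`, `partial_b`, the per-side classification
#'   tables, counts, and unrounded percentages.
#' @export
compare_cell_types <- function(samples_a, samples_b, min_overlap = 1L,
                               direction = c("both", "a_only"),
                               cell_type_a = NULL, cell_type_b = NULL) {
  direction <- match.arg(direction)
  cons_a <- build_consensus(samples_a, cell_type_a)
  cons_b <- build_consensus(samples_b, cell_type_b)
  lab_a <- classify_against(cons_a, samples_b, min_overlap)
  take <- function(df, lab) {
    out <- df[df$label == lab, c("chrom", "start", "end"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (direction == "both") {
    lab_b <- classify_against(cons_b, samples_a, min_overlap)
    cmr <- merge_intervals(rbind(take(lab_a, "CMR"), take(lab_b, "CMR")))
    dmr_b <- take(lab_b, "DMR")
    partial_b <- take(lab_b, "PARTIAL")
  } else {
    lab_b <- NULL
    cmr <- take(lab_a, "CMR")
    dmr_b <- empty
    partial_b <- empty
  }
  dmr_a <- take(lab_a, "DMR")
  counts <- c(dmr_a = nrow(dmr_a), dmr_b = nrow(dmr_b), cmr = nrow(cmr))
  n_total <- sum(counts)
  pct <- if (n_total > 0) {
    summarize_comparison(counts[["dmr_a"]], counts[["dmr_b"]], n_total)
  } else {
    c(pct_dmr_a = NA_real_, pct_dmr_b = NA_real_, pct_cmr = NA_real_)
  }
  structure(list(
    cell_type_a = cons_a$cell_type, cell_type_b = cons_b$cell_type,
    n_replicates_a = cons_a$n_replicates, n_replicates_b = cons_b$n_replicates,
    direction = direction, min_overlap = as.integer(min_overlap),
    dmr_a = dmr_a, dmr_b = dmr_b, cmr = cmr,
    partial_a = take(lab_a, "PARTIAL"), partial_b = partial_b,
    labels_a = lab_a, labels_b = lab_b,
    counts = counts, n_total = n_total, percentages = pct),
    class = "dmr_comparison")
}

#' DMR/CMR percentages from counts
#'
#' Converts a DMR/CMR partition into percentages of the total region count:
#' `pct_x = 100 * n_x / n_total`, with the CMR share as the remainder. Values
#' are returned unrounded; reports round half-up to one decimal.
#'
#' @param n_dmr_a,n_dmr_b Counts of cell-type-specific DMRs.
#' @param n_total Total regions in the comparison (DMR-A + DMR-B + CMR).
#' @return Named numeric vector `pct_dmr_a`, `pct_dmr_b`, `pct_cmr`.
#' @examples
#' summarize_comparison(17371, 1934, 43458) # ~ 40 / 4.4 / 55.6
#' @export
summarize_comparison <- function(n_dmr_a, n_dmr_b, n_total) {
  if (n_total == 0) stop("summary undefined: n_total is 0", call. = FALSE)
  if (n_dmr_a < 0 || n_dmr_b < 0 || n_dmr_a + n_dmr_b > n_total) {
    stop("need 0 <= n_dmr_a + n_dmr_b <= n_total", call. = FALSE)
  }
  c(pct_dmr_a = 100 * n_dmr_a / n_total,
    pct_dmr_b = 100 * n_dmr_b / n_total,
    pct_cmr = 100 * (n_total - n_dmr_a - n_dmr_b) / n_total)
}

#' Round half away from zero
#'
#' Report-layer rounding: 0.45 -> 0.5 at one decimal, unlike base R's
#' round-half-even. Used when printing percentages.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.dmr_comparison <- function(x, ...) {
  cat(sprintf("Comparison of methylated regions: %s vs %s (%d vs %d replicates)\n",
              x$cell_type_a, x$cell_type_b,
              x$n_replicates_a, x$n_replicates_b))
  s <- summary(x)
  cat(sprintf("  total regions (DMR+CMR): %d\n", s$n_total))
  cat(sprintf("  DMR specific to %-12s %6d (%s%%)\n", x$cell_type_a,
              s$counts[["dmr_a"]], format(s$pct_rounded[["pct_dmr_a"]])))
  cat(sprintf("  DMR specific to %-12s %6d (%s%%)\n", x$cell_type_b,
              s$counts[["dmr_b"]], format(s$pct_rounded[["pct_dmr_b"]])))
  cat(sprintf("  CMR (common)             %6d (%s%%)\n",
              s$counts[["cmr"]], format(s$pct_rounded[["pct_cmr"]])))
  cat(sprintf("  partial (excluded):      %d (A-side) + %d (B-side)\n",
              nrow(x$partial_a), nrow(x$partial_b)))
  invisible(x)
}

#' @export
summary.dmr_comparison <- function(object, ...) {
  list(cell_type_a = object$cell_type_a, cell_type_b = object$cell_type_b,
       counts = object$counts, n_total = object$n_total,
       n_partial_a = nrow(object$partial_a),
       n_partial_b = nrow(object$partial_b),
       percentages = object$percentages,
       pct_rounded = round_half_up(object$percentages, 1))
}
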