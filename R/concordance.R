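#' Replicate concordance between two region sets
#'
#' The concordance proportion used to judge dispersion between biological
#' replicates of one cell type: the number of regions (counted from both
#' samples) that overlap at least one region of the other sample, divided by
#' the total number of regions detected in the two samples. Identical samples
#' score 1, fully disjoint samples score 0.
#'
#' @param a,b `region_set`s.
#' @param min_overlap Minimum shared base pairs for two regions to count as
#'   overlapping (default 1).
#' @return A one-row data frame: `sample_a`, `sample_b`, `n_a`, `n_b`,
#'   `n_a_overlapping`, `n_b_overlapping`, `proportion`.
#' @export
pairwise_concordance <- function(a, b, min_overlap = 1L) {
  n_a <- n_regions(a)
  n_b <- n_regions(b)
  if (n_a + n_b == 0) {
    stop("concordance undefined: both samples have zero regions", call. = FALSE)
  }
  n_a_ov <- n_regions(overlap_filter(a, b, min_overlap))
  n_b_ov <- n_regions(overlap_filter(b, a, min_overlap))
  data.frame(sample_a = a$sample_id, sample_b = b$sample_id,
             n_a = n_a, n_b = n_b,
             n_a_overlapping = n_a_ov, n_b_overlapping = n_b_ov,
             proportion = (n_a_ov + n_b_ov) / (n_a + n_b),
             stringsAsFactors = FALSE)
}

#' Concordance for all unordered pairs of samples
#'
#' @param samples A list of `region_set`s (>= 2), typically the biological
#'   replicates of one cell type.
#' @param min_overlap Passed to [pairwise_concordance()].
#' @return A data frame with one row per unordered pair.
#' @export
concordance_matrix <- function(samples, min_overlap = 1L) {
  if (!is.list(samples) || length(samples) < 2) {
    stop("need at least 2 samples", call. = FALSE)
  }
  n <- length(samples)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      rows[[length(rows) + 1]] <-
        pairwise_concordance(samples[[i]], samples[[j]], min_overlap)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
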