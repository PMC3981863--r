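# Independent oracles used across the suite.
#
# Interval operations are checked against a per-base bitmap: on a toy genome
# every base is a logical cell, set algebra becomes elementwise &/|, and
# intervals are recovered by run-length encoding. The bitmap path shares no
# code with the package's interval engine.

# df: chrom/start/end (0-based half-open); genome: named lengths
bitmap_of <- function(df, genome) {
  bm <- lapply(genome, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    bm[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bm
}

bitmap_to_intervals <- function(bm) {
  rows <- lapply(names(bm), function(ch) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

bitmap_and <- function(a, b) Map(`&`, a, b)
bitmap_or <- function(a, b) Map(`|`, a, b)

oracle_merge <- function(df, genome) bitmap_to_intervals(bitmap_of(df, genome))

oracle_intersect <- function(a, b, genome) {
  bitmap_to_intervals(bitmap_and(bitmap_of(a, genome), bitmap_of(b, genome)))
}

# O(n*m) all-pairs presence scan
oracle_overlap_filter <- function(q, s, min_overlap = 1) {
  keep <- vapply(seq_len(nrow(q)), function(i) {
    ov <- pmin(q$end[i], s$end) - pmax(q$start[i], s$start)
    any(s$chrom == q$chrom[i] & ov >= min_overlap)
  }, logical(1))
  out <- q[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_consensus <- function(dfs, genome) {
  bm <- bitmap_of(dfs[[1]], genome)
  for (d in dfs[-1]) bm <- bitmap_and(bm, bitmap_of(d, genome))
  bm
}

# presence of any single covered base of `bm` inside [start, end) suffices
# (min_overlap = 1 semantics)
bitmap_presence <- function(region, bm) {
  any(bm[[region$chrom]][(region$start + 1):region$end])
}

# full DMR/CMR/PARTIAL comparison evaluated purely on bitmaps
oracle_compare <- function(dfs_a, dfs_b, genome) {
  bms_a <- lapply(dfs_a, bitmap_of, genome = genome)
  bms_b <- lapply(dfs_b, bitmap_of, genome = genome)
  and_all <- function(bms) Reduce(bitmap_and, bms)
  classify <- function(cons_bm, other_bms) {
    regions <- bitmap_to_intervals(cons_bm)
    if (nrow(regions) == 0) {
      regions$label <- character(0)
      return(regions)
    }
    supp <- vapply(seq_len(nrow(regions)), function(i) {
      sum(vapply(other_bms, function(bm)
        bitmap_presence(regions[i, ], bm), logical(1)))
    }, numeric(1))
    regions$label <- ifelse(supp == 0, "DMR",
                            ifelse(supp == length(other_bms), "CMR", "PARTIAL"))
    regions
  }
  lab_a <- classify(and_all(bms_a), bms_b)
  lab_b <- classify(and_all(bms_b), bms_a)
  cmr_bm <- bitmap_of(rbind(lab_a[lab_a$label == "CMR", 1:3],
                            lab_b[lab_b$label == "CMR", 1:3]), genome)
  list(dmr_a = lab_a[lab_a$label == "DMR", 1:3],
       dmr_b = lab_b[lab_b$label == "DMR", 1:3],
       cmr = bitmap_to_intervals(cmr_bm),
       partial_a = lab_a[lab_a$label == "PARTIAL", 1:3],
       partial_b = lab_b[lab_b$label == "PARTIAL", 1:3])
}

# brute-force BH step-up: for every p_i, the smallest (m * t / #{p <= t})
# over candidate thresholds t >= p_i
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

random_intervals <- function(n, genome, max_len = 500) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(genome[[chrom[i]]] - len[i] + 1, 1) - 1L
  }, integer(1))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

expect_same_intervals <- function(got, want) {
  got <- got[order(got$chrom, got$start), c("chrom", "start", "end")]
  want <- want[order(want$chrom, want$start), c("chrom", "start", "end")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
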