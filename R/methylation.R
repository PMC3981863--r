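#' Validate a per-CpG methylation table
#'
#' Rows are (clone_id, group, locus, cpg_index, methylation_pct), one row
#' per sequenced CpG per clone, with percentages in \[0, 100\] and
#' (clone_id, locus, cpg_index) unique.
#'
#' @param table Data frame with the columns above.
#' @return The validated data frame, invisibly classed `methylation_table`.
#' @export
methylation_table <- function(table) {
  need <- c("clone_id", "group", "locus", "cpg_index", "methylation_pct")
  stopifnot(all(need %in% names(table)))
  if (any(table$methylation_pct < 0 | table$methylation_pct > 100)) {
    stop("methylation_pct outside [0, 100]", call. = FALSE)
  }
  key <- paste(table$clone_id, table$locus, table$cpg_index)
  if (anyDuplicated(key)) {
    stop("duplicate (clone_id, locus, cpg_index) row", call. = FALSE)
  }
  class(table) <- unique(c("methylation_table", class(table)))
  table
}

clone_means <- function(table, locus) {
  tab <- table[table$locus == locus, , drop = FALSE]
  if (nrow(tab) == 0) stop("locus not in table: ", locus, call. = FALSE)
  agg <- stats::aggregate(methylation_pct ~ clone_id + group, data = tab,
                          FUN = mean)
  names(agg)[names(agg) == "methylation_pct"] <- "clone_mean"
  agg
}

#' Group methylation summaries at a locus
#'
#' Two-stage averaging matching the way pyrosequencing panels are reported:
#' CpG percentages are first averaged within each clone, then clone means
#' are summarized per group as mean and sample standard deviation (n-1
#' denominator). A single-clone group reports sd 0 with `n = 1` flagging
#' that the dispersion is undefined.
#'
#' @param table A methylation table (see [methylation_table()]).
#' @param locus Locus name to summarize.
#' @return Data frame: `locus`, `group`, `mean`, `sd`, `n`.
#' @export
summarize_methylation <- function(table, locus) {
  cm <- clone_means(table, locus)
  groups <- unique(cm$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- cm$clone_mean[cm$group == g]
    data.frame(locus = locus, group = g, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare methylation between two groups at a locus
#'
#' Student's pooled-variance two-sample t-test on per-clone mean methylation
#' (the clone, not the CpG, is the statistical unit).
#'
#' @param table A methylation table.
#' @param locus Locus name.
#' @param group_a,group_b Group labels to compare (>= 2 clones each).
#' @return List with `t`, `df`, `p_value`, and the two group means.
#' @export
compare_methylation <- function(table, locus, group_a, group_b) {
  cm <- clone_means(table, locus)
  va <- cm$clone_mean[cm$group == group_a]
  vb <- cm$clone_mean[cm$group == group_b]
  if (length(va) < 2 || length(vb) < 2) {
    stop("need at least 2 clones per group", call. = FALSE)
  }
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    # degenerate: no within-group variation
    eq <- mean(va) == mean(vb)
    return(list(t = if (eq) 0 else sign(mean(va) - mean(vb)) * Inf,
                df = length(va) + length(vb) - 2,
                p_value = if (eq) 1 else 0,
                mean_a = mean(va), mean_b = mean(vb)))
  }
  tt <- stats::t.test(va, vb, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(va), mean_b = mean(vb))
}
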