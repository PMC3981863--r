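#' Percentile-shift normalization of expression intensities
#'
#' The microarray normalization used by GeneSpring's "percentile shift"
#' preset: intensities are log2-transformed and each sample's log2 values are
#' shifted by a constant so that its chosen percentile (default the 75th)
#' equals the across-sample median of those percentiles. Only per-sample
#' offsets are applied, so within-sample relative differences are preserved
#' and a sample rescaled by any constant factor normalizes back onto the
#' original.
#'
#' @param mat Numeric matrix, probes x samples. Linear-scale values must be
#'   strictly positive; a matrix already carrying the `"log2"` attribute
#'   (i.e. output of this function) is shifted without re-transforming,
#'   making the operation idempotent.
#' @param percentile Percentile (0-100) to align across samples; default 75.
#' @return The normalized log2-scale matrix, with attribute `log2 = TRUE`.
#' @export
percentile_shift_normalize <- function(mat, percentile = 75) {
  stopifnot(is.matrix(mat), is.numeric(mat), percentile > 0, percentile < 100)
  if (isTRUE(attr(mat, "log2"))) {
    lg <- mat
  } else {
    if (any(mat <= 0)) {
      stop("intensities must be strictly positive on the linear scale",
           call. = FALSE)
    }
    lg <- log2(mat)
  }
  q <- apply(lg, 2, stats::quantile, probs = percentile / 100, names = FALSE)
  target <- stats::median(q)
  out <- sweep(lg, 2, q - target, "-")
  attr(out, "log2") <- TRUE
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q-values controlling the false discovery rate: on sorted p-values,
#' q_(i) = min over j >= i of (m/j) * p_(j), capped at 1 and mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q
}

## Vectorised two-sample t-test across matrix rows.
## Zero pooled variance: p = 1 when the means agree, p = 0 when they differ.
row_t_test <- function(mat, idx_a, idx_b, var_equal = TRUE) {
  na <- length(idx_a); nb <- length(idx_b)
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(se)
  if (any(degenerate)) {
    eq <- degenerate & (ma == mb)
    p[degenerate] <- 0
    p[eq] <- 1
    tstat[eq] <- 0
    tstat[degenerate & !eq] <- sign(ma - mb)[degenerate & !eq] * Inf
  }
  list(mean_a = ma, mean_b = mb, t = tstat, df = df, p = p)
}

#' Two-group differential expression screen
#'
#' Per probe: Student's two-sample t-test (pooled variance by default) on
#' normalized log2 intensities, Benjamini-Hochberg adjustment across all
#' probes, then the joint filter of the published screen: a probe is called
#' up or down only when `|log2 fold change| > log2(fc_threshold)` AND
#' `q < q_threshold`. "Up" means higher in group A.
#'
#' @param mat Normalized log2-scale matrix, probes x samples.
#' @param group_a,group_b Column names or indices of the two groups
#'   (>= 2 samples each).
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param var_equal `TRUE` (default) for the pooled-variance Student test;
#'   `FALSE` for Welch.
#' @return A `de_screen` data frame: `probe`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `t`, `p_value`, `q_value`, `status` in
#'   `{up, down, not_significant}`.
#' @export
two_group_screen <- function(mat, group_a, group_b, fc_threshold = 2,
                             q_threshold = 0.05, var_equal = TRUE) {
  stopifnot(is.matrix(mat))
  idx_a <- if (is.character(group_a)) match(group_a, colnames(mat)) else group_a
  idx_b <- if (is.character(group_b)) match(group_b, colnames(mat)) else group_b
  if (anyNA(idx_a) || anyNA(idx_b)) stop("unknown sample name", call. = FALSE)
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  tt <- row_t_test(mat, idx_a, idx_b, var_equal)
  q <- bh_adjust(tt$p)
  lfc <- tt$mean_a - tt$mean_b
  sig <- abs(lfc) > log2(fc_threshold) & q < q_threshold
  status <- ifelse(!sig, "not_significant", ifelse(lfc > 0, "up", "down"))
  probes <- rownames(mat)
  if (is.null(probes)) probes <- sprintf("probe_%d", seq_len(nrow(mat)))
  out <- data.frame(probe = probes, mean_a = tt$mean_a, mean_b = tt$mean_b,
                    log2_fold_change = lfc, t = tt$t,
                    p_value = tt$p, q_value = q, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("de_screen", "data.frame")
  out
}

#' @export
print.de_screen <- function(x, ...) {
  cat(sprintf(
    "Two-group expression screen: %d probes (|FC| > %g, q < %g)\n",
    nrow(x), attr(x, "fc_threshold"), attr(x, "q_threshold")))
  cat(sprintf("  up: %d   down: %d   not significant: %d\n",
              sum(x$status == "up"), sum(x$status == "down"),
              sum(x$status == "not_significant")))
  invisible(x)
}

#' @export
summary.de_screen <- function(object, ...) {
  c(n_probes = nrow(object),
    n_up = sum(object$status == "up"),
    n_down = sum(object$status == "down"))
}

#' Hierarchical clustering of sample expression profiles
#'
#' Agglomerative average-linkage clustering with distance
#' 1 - Pearson correlation between sample (column) profiles.
#'
#' @param mat Numeric matrix, probes x samples (>= 2 samples).
#' @return An `stats::hclust` object.
#' @export
hierarchical_cluster <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(mat)[which(sds == 0)[1]]
    if (is.null(nm)) nm <- paste("column", which(sds == 0)[1])
    stop("zero-variance sample profile: ", nm, call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  stats::hclust(d, method = "average")
}

#' Relative expression from qPCR Ct values (delta-delta-Ct)
#'
#' Per sample, the level is `2^-(Ct_target - Ct_reference)`; all levels are
#' then divided by the mean level of the calibrator samples, so the
#' calibrator group averages exactly 1 (e.g. "the average of the ES cell
#' clones was set at 1").
#'
#' @param ct_target,ct_reference Named numeric vectors of Ct values for the
#'   gene of interest and the reference gene (e.g. Gapdh), same samples.
#' @param calibrator_samples Names (or indices) of the calibrator samples.
#' @return Named vector of relative expression levels.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     calibrator_samples) {
  stopifnot(length(ct_target) == length(ct_reference),
            all(is.finite(ct_target)), all(is.finite(ct_reference)))
  if (length(calibrator_samples) == 0) {
    stop("calibrator sample set is empty", call. = FALSE)
  }
  level <- 2^-(ct_target - ct_reference)
  cal <- if (is.character(calibrator_samples)) {
    level[calibrator_samples]
  } else {
    level[calibrator_samples]
  }
  if (anyNA(cal)) stop("unknown calibrator sample", call. = FALSE)
  level / mean(cal)
}
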