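#' Configuration for the peak-set simulator
#'
#' Describes the world the generator emulates: a catalog of true methylated
#' regions (shared between two cell types or specific to one), imperfectly
#' re-detected in each biological replicate with boundary jitter and
#' spurious extra regions. Region lengths default to enrichment-peak scale
#' (500-2000 bp); boundary jitter defaults to sonicated-fragment scale
#' (about 100-300 bp fragments, sd 100 bp); per-replicate detection
#' probability defaults to 0.8, which yields replicate-concordance
#' proportions in the 60-80% range typical of enrichment sequencing.
#'
#' @param seed Integer RNG seed.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param n_shared,n_specific_a,n_specific_b True region counts per label.
#' @param region_length_range Min/max true region length in bp.
#' @param min_gap Minimum separation between true regions in bp.
#' @param n_replicates_a,n_replicates_b Replicates per cell type.
#' @param p_detect Per-region, per-replicate detection probability.
#' @param boundary_jitter_sd SD (bp) of the rounded Gaussian endpoint jitter.
#' @param fp_rate Expected false-positive regions per replicate (Poisson).
#' @param cell_type_a,cell_type_b Cell-type labels for the two sides.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                              n_shared = 200L, n_specific_a = 50L,
                              n_specific_b = 30L,
                              region_length_range = c(500L, 2000L),
                              min_gap = 1000L,
                              n_replicates_a = 3L, n_replicates_b = 3L,
                              p_detect = 0.8, boundary_jitter_sd = 100,
                              fp_rate = 20,
                              cell_type_a = "iPS_Aid_WT",
                              cell_type_b = "iPS_Aid_KO") {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0),
            n_shared >= 0, n_specific_a >= 0, n_specific_b >= 0,
            length(region_length_range) == 2,
            region_length_range[1] >= 1,
            region_length_range[1] <= region_length_range[2],
            min_gap >= 0, n_replicates_a >= 1, n_replicates_b >= 1,
            p_detect >= 0, p_detect <= 1, boundary_jitter_sd >= 0,
            fp_rate >= 0)
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_shared = as.integer(n_shared),
                 n_specific_a = as.integer(n_specific_a),
                 n_specific_b = as.integer(n_specific_b),
                 region_length_range = as.integer(region_length_range),
                 min_gap = as.integer(min_gap),
                 n_replicates_a = as.integer(n_replicates_a),
                 n_replicates_b = as.integer(n_replicates_b),
                 p_detect = p_detect,
                 boundary_jitter_sd = boundary_jitter_sd,
                 fp_rate = fp_rate,
                 cell_type_a = cell_type_a, cell_type_b = cell_type_b),
            class = "simulation_config")
}

## Rejection-sample one interval that keeps >= gap bp away from all rows of
## `occupied` (data frame chrom/start/end); NULL if the cap is exhausted.
place_region <- function(chrom_lengths, len_range, occupied, gap,
                         max_tries = 1000L) {
  chroms <- names(chrom_lengths)
  pchrom <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_len(max_tries)) {
    chrom <- sample(chroms, 1, prob = pchrom)
    len <- sample(seq(len_range[1], len_range[2]), 1)
    lmax <- chrom_lengths[[chrom]] - len
    if (lmax < 0) next
    start <- floor(stats::runif(1, 0, lmax + 1))
    end <- start + len
    clash <- occupied$chrom == chrom &
      start < occupied$end + gap & occupied$start - gap < end
    if (!any(clash)) {
      return(data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(end), stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Draw the ground-truth region catalog
#'
#' Places `n_shared + n_specific_a + n_specific_b` non-overlapping true
#' regions uniformly on the genome, pairwise separated by at least
#' `min_gap` bp, and labels them `shared`, `specific_a`, `specific_b`.
#' Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return A `simulation_truth` object: `regions` data frame (`chrom`,
#'   `start`, `end`, `label`) plus the config.
#' @export
simulate_region_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_total <- config$n_shared + config$n_specific_a + config$n_specific_b
  acc <- data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_total)) {
    r <- place_region(config$chrom_lengths, config$region_length_range,
                      acc, config$min_gap)
    if (is.null(r)) {
      stop(sprintf(
        "genome too small: placed %d of %d regions before hitting the retry cap",
        i - 1, n_total), call. = FALSE)
    }
    acc <- rbind(acc, r)
  }
  label <- rep(c("shared", "specific_a", "specific_b"),
               c(config$n_shared, config$n_specific_a, config$n_specific_b))
  acc$label <- label
  o <- order(acc$chrom, acc$start)
  acc <- acc[o, ]
  rownames(acc) <- NULL
  structure(list(regions = acc, config = config), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d regions (%d shared, %d specific_a, %d specific_b)\n",
              nrow(x$regions), sum(x$regions$label == "shared"),
              sum(x$regions$label == "specific_a"),
              sum(x$regions$label == "specific_b")))
  invisible(x)
}

jitter_regions <- function(df, sd, chrom_lengths) {
  if (sd == 0 || nrow(df) == 0) return(df)
  js <- round(stats::rnorm(nrow(df), 0, sd))
  je <- round(stats::rnorm(nrow(df), 0, sd))
  ns <- pmax(df$start + js, 0)
  ne <- pmin(df$end + je, chrom_lengths[df$chrom])
  # truncation rule: a jitter draw that would invert an interval is dropped
  bad <- ns >= ne
  ns[bad] <- df$start[bad]
  ne[bad] <- df$end[bad]
  df$start <- as.integer(ns)
  df$end <- as.integer(ne)
  df
}

#' Simulate replicate peak sets from a truth catalog
#'
#' Each replicate of cell type A observes every `shared`/`specific_a` truth
#' region independently with probability `p_detect`, with endpoints jittered
#' by rounded Gaussian noise, plus `Poisson(fp_rate)` false-positive regions
#' placed uniformly in truth-free parts of the genome; symmetrically for B.
#' Deterministic for a fixed config seed.
#'
#' @param truth A [simulate_region_truth()] result.
#' @param config The corresponding [simulation_config()] (defaults to the
#'   one stored in `truth`).
#' @return List with `samples_a` and `samples_b`, each a list of
#'   `region_set`s labeled by cell type.
#' @export
simulate_replicates <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "simulation_truth"))
  # fixed offset so the replicate stream is decoupled from truth placement
  set.seed(config$seed + 1L)
  make_side <- function(own_label, cell_type, n_reps) {
    eligible <- truth$regions[truth$regions$label %in% c("shared", own_label),
                              c("chrom", "start", "end")]
    lapply(seq_len(n_reps), function(r) {
      det <- stats::runif(nrow(eligible)) < config$p_detect
      obs <- jitter_regions(eligible[det, , drop = FALSE],
                            config$boundary_jitter_sd, config$chrom_lengths)
      n_fp <- stats::rpois(1, config$fp_rate)
      fps <- list()
      for (k in seq_len(n_fp)) {
        fp <- place_region(config$chrom_lengths, config$region_length_range,
                           truth$regions, gap = 0L)
        if (!is.null(fp)) fps[[length(fps) + 1]] <- fp
      }
      df <- rbind(obs, do.call(rbind, fps))
      if (is.null(df)) {
        df <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
      }
      region_set(df, sample_id = sprintf("%s_rep%d", cell_type, r),
                 cell_type = cell_type)
    })
  }
  list(samples_a = make_side("specific_a", config$cell_type_a,
                             config$n_replicates_a),
       samples_b = make_side("specific_b", config$cell_type_b,
                             config$n_replicates_b))
}

#' Simulate a probe-by-sample expression matrix with planted effects
#'
#' Baseline log2 intensities are drawn once per probe, a signed offset of
#' `log2fc` is applied to the planted up-/down-regulated probes in group A,
#' Gaussian noise is added per cell, and the matrix is exported on the
#' linear scale (2^x) so the normalization stage is exercised. Planting
#' counts default to the published screen's 26 up / 12 down among 54,497
#' probes (six clones per group).
#'
#' @param n_probes Total probes.
#' @param n_up,n_down Probes planted higher/lower in group A.
#' @param log2fc Absolute planted log2 fold change.
#' @param noise_sd Per-cell Gaussian noise sd on the log2 scale.
#' @param n_per_group Samples per group.
#' @param seed Integer RNG seed.
#' @param baseline_mean,baseline_sd Distribution of per-probe baseline
#'   log2 intensity.
#' @param group_names Labels for groups A and B.
#' @return List: `matrix` (linear scale, probes x samples), `groups` (named
#'   character vector sample -> group), `truth` (data frame `probe`,
#'   `direction`, `log2fc` of planted probes).
#' @export
simulate_expression <- function(n_probes = 54497L, n_up = 26L, n_down = 12L,
                                log2fc = 3, noise_sd = 0.25,
                                n_per_group = 6L, seed = 1L,
                                baseline_mean = 8, baseline_sd = 2,
                                group_names = c("A", "B")) {
  if (n_up + n_down > n_probes) {
    stop("n_up + n_down exceeds n_probes", call. = FALSE)
  }
  stopifnot(n_probes >= 1, n_up >= 0, n_down >= 0, n_per_group >= 2,
            noise_sd >= 0, length(group_names) == 2)
  set.seed(seed)
  probes <- sprintf("probe_%05d", seq_len(n_probes))
  planted <- sample.int(n_probes, n_up + n_down)
  up <- planted[seq_len(n_up)]
  down <- planted[seq_len(n_down) + n_up]
  baseline <- stats::rnorm(n_probes, baseline_mean, baseline_sd)
  offset_a <- numeric(n_probes)
  offset_a[up] <- log2fc
  offset_a[down] <- -log2fc
  n_samples <- 2L * n_per_group
  group <- rep(group_names, each = n_per_group)
  samples <- sprintf("%s_%d", group, rep(seq_len(n_per_group), 2))
  lg <- matrix(baseline, n_probes, n_samples) +
    outer(offset_a, as.numeric(group == group_names[1])) +
    matrix(stats::rnorm(n_probes * n_samples, 0, noise_sd),
           n_probes, n_samples)
  dimnames(lg) <- list(probes, samples)
  truth <- data.frame(
    probe = probes[c(up, down)],
    direction = rep(c("up", "down"), c(n_up, n_down)),
    log2fc = rep(c(log2fc, -log2fc), c(n_up, n_down)),
    stringsAsFactors = FALSE)
  list(matrix = 2^lg, groups = stats::setNames(group, samples),
       truth = truth[order(truth$probe), , drop = FALSE])
}

#' Simulate a per-clone CpG methylation table
#'
#' Per CpG, the methylation percentage is Gaussian around the clone's group
#' mean, clipped to \[0, 100\]. Deterministic for a fixed seed.
#'
#' @param group_means Named numeric vector, group label -> mean methylation
#'   percent (each in \[0, 100\]).
#' @param n_clones Clones per group.
#' @param n_cpgs CpGs per clone at the locus.
#' @param sd Gaussian sd of per-CpG values.
#' @param locus Locus name.
#' @param seed Integer RNG seed.
#' @return A `methylation_table` data frame.
#' @export
simulate_methylation <- function(group_means, n_clones = 3L, n_cpgs = 4L,
                                 sd = 5, locus = "locus1", seed = 1L) {
  if (any(group_means < 0 | group_means > 100)) {
    stop("group means must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(!is.null(names(group_means)), n_clones >= 1, n_cpgs >= 1, sd >= 0)
  set.seed(seed)
  rows <- expand.grid(cpg_index = seq_len(n_cpgs), clone = seq_len(n_clones),
                      group = names(group_means), stringsAsFactors = FALSE)
  mu <- group_means[rows$group]
  val <- pmin(100, pmax(0, stats::rnorm(nrow(rows), mu, sd)))
  methylation_table(data.frame(
    clone_id = sprintf("%s_clone%d", rows$group, rows$clone),
    group = rows$group, locus = locus, cpg_index = rows$cpg_index,
    methylation_pct = val, stringsAsFactors = FALSE))
}
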