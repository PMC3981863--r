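## Run-directory orchestration: each run_* writes plain-text artifacts plus a
## JSON provenance block so results are diffable and reproducible.

write_provenance <- function(path, params) {
  params$package <- "mbdmr"
  params$version <- as.character(utils::packageVersion("mbdmr"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic run directory
#'
#' Writes every input the pipeline consumes: per-replicate peak BED files
#' with a sample sheet, the ground-truth region catalog, a linear-scale
#' expression matrix with planted differential probes and its truth list,
#' a per-clone CpG methylation table, and the echoed configuration as JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param expression_args,methylation_args Optional named lists overriding
#'   [simulate_expression()] / [simulate_methylation()] defaults; their
#'   seeds default to the config seed.
#' @return Invisibly, a list of the written file paths and the truth objects.
#' @export
run_simulate <- function(out_dir, config = simulation_config(),
                         expression_args = list(),
                         methylation_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  truth <- simulate_region_truth(config)
  reps <- simulate_replicates(truth, config)
  all_samples <- c(reps$samples_a, reps$samples_b)
  bed_paths <- character(0)
  sheet <- data.frame(sample_id = character(), cell_type = character(),
                      path = character(), stringsAsFactors = FALSE)
  for (s in all_samples) {
    p <- file.path(out_dir, paste0(s$sample_id, ".bed"))
    write_bed(s, p)
    bed_paths <- c(bed_paths, p)
    sheet <- rbind(sheet, data.frame(sample_id = s$sample_id,
                                     cell_type = s$cell_type,
                                     path = basename(p),
                                     stringsAsFactors = FALSE))
  }
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  write_tsv(sheet, sheet_path)
  write_tsv(truth$regions, file.path(out_dir, "truth_regions.tsv"))

  ea <- utils::modifyList(list(seed = config$seed), expression_args)
  expr <- do.call(simulate_expression, ea)
  emat <- data.frame(probe = rownames(expr$matrix), expr$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(emat, file.path(out_dir, "expression.tsv"))
  write_tsv(data.frame(sample = names(expr$groups), group = expr$groups,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "expression_groups.tsv"))
  write_tsv(expr$truth, file.path(out_dir, "expression_truth.tsv"))

  ma <- utils::modifyList(
    list(group_means = c(group_a = 80, group_b = 15), seed = config$seed),
    methylation_args)
  meth <- do.call(simulate_methylation, ma)
  write_tsv(as.data.frame(meth), file.path(out_dir, "methylation.tsv"))

  cfg <- unclass(config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  write_provenance(file.path(out_dir, "config.json"), list(
    subcommand = "simulate", seed = config$seed, config = cfg))
  invisible(list(sample_sheet = sheet_path, beds = bed_paths,
                 truth = truth, replicates = reps, expression = expr,
                 methylation = meth, out_dir = out_dir))
}

#' Read a sample sheet and its BED files
#'
#' The sheet is a header-ed TSV with columns `sample_id`, `cell_type`,
#' `path`; relative paths are resolved against the sheet's directory.
#'
#' @param sample_sheet Path to the sheet.
#' @return Named list of `region_set`s.
#' @export
read_sample_sheet <- function(sample_sheet) {
  sheet <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "cell_type", "path") %in% names(sheet)))
  base <- dirname(sample_sheet)
  samples <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_bed(p, sample_id = sheet$sample_id[i],
             cell_type = sheet$cell_type[i])
  })
  stats::setNames(samples, sheet$sample_id)
}

#' Run the two-cell-type comparison from a sample sheet
#'
#' Reads the per-sample BED files, builds both consensuses, classifies
#' DMR/CMR/PARTIAL, and writes `dmr_a.bed`, `dmr_b.bed`, `cmr.bed`,
#' `partial_a.bed`, `partial_b.bed`, a region-level listing `regions.tsv`
#' (chrom, start, end, side, label), per-sample counts
#' `sample_counts.tsv`, and `summary.json` with counts, percentages and
#' the parameters used.
#'
#' @param sample_sheet Sample sheet TSV listing exactly two cell types.
#' @param out_dir Output directory.
#' @param min_overlap Minimum shared base pairs for presence (default 1).
#' @param direction `"both"` or `"a_only"` (one-directional consensus
#'   classification).
#' @return Invisibly, the `dmr_comparison` object.
#' @export
run_compare <- function(sample_sheet, out_dir, min_overlap = 1L,
                        direction = c("both", "a_only")) {
  direction <- match.arg(direction)
  samples <- read_sample_sheet(sample_sheet)
  types <- vapply(samples, function(s) s$cell_type, character(1))
  ut <- unique(types)
  if (length(ut) != 2) {
    stop("sample sheet must list exactly two cell types, found: ",
         paste(ut, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_cell_types(samples[types == ut[1]], samples[types == ut[2]],
                            min_overlap = min_overlap, direction = direction)
  for (nm in c("dmr_a", "dmr_b", "cmr", "partial_a", "partial_b")) {
    write_bed(cmp[[nm]], file.path(out_dir, paste0(nm, ".bed")))
  }
  lab_rows <- function(df, side) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               side = side, label = df$label,
               n_other_supporting = df$n_other_supporting,
               stringsAsFactors = FALSE)
  }
  regions <- rbind(lab_rows(cmp$labels_a, ut[1]), lab_rows(cmp$labels_b, ut[2]))
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), side = character(),
                          label = character(), n_other_supporting = integer())
  }
  write_tsv(regions, file.path(out_dir, "regions.tsv"))
  write_tsv(data.frame(sample_id = names(samples), cell_type = types,
                       n_regions = vapply(samples, n_regions, integer(1)),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "sample_counts.tsv"))
  s <- summary(cmp)
  write_provenance(file.path(out_dir, "summary.json"), list(
    subcommand = "compare",
    cell_type_a = cmp$cell_type_a, cell_type_b = cmp$cell_type_b,
    n_replicates_a = cmp$n_replicates_a, n_replicates_b = cmp$n_replicates_b,
    counts = as.list(cmp$counts), n_total = cmp$n_total,
    n_partial_a = s$n_partial_a, n_partial_b = s$n_partial_b,
    percentages = as.list(cmp$percentages),
    percentages_rounded = as.list(s$pct_rounded),
    parameters = list(min_overlap = as.integer(min_overlap),
                      direction = direction)))
  invisible(cmp)
}

#' Replicate-concordance report per cell type
#'
#' For each cell type in the sheet with at least two samples, computes all
#' unordered pairwise concordance proportions and writes `concordance.tsv`.
#'
#' @param sample_sheet Sample sheet TSV.
#' @param out_dir Output directory.
#' @param min_overlap Minimum shared base pairs for presence.
#' @return Invisibly, the concordance data frame.
#' @export
run_concordance <- function(sample_sheet, out_dir, min_overlap = 1L) {
  samples <- read_sample_sheet(sample_sheet)
  types <- vapply(samples, function(s) s$cell_type, character(1))
  rows <- list()
  for (ct in unique(types)) {
    grp <- samples[types == ct]
    if (length(grp) < 2) next
    cm <- concordance_matrix(grp, min_overlap)
    cm <- cbind(cell_type = ct, cm, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- cm
  }
  if (length(rows) == 0) {
    stop("no cell type has >= 2 samples", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(out, file.path(out_dir, "concordance.tsv"))
  invisible(out)
}

fmt_pct <- function(x) {
  r <- round_half_up(x, 1)
  ifelse(r == round(r), sprintf("%d%%", as.integer(round(r))),
         sprintf("%.1f%%", r))
}

#' Render the human-readable comparison report
#'
#' Reads `summary.json` from a completed compare run and writes
#' `report.tsv` (category, count, percent) plus `report.txt`, with
#' percentages rounded half-up to one decimal (whole percentages printed
#' without decimals). Re-running produces identical bytes.
#'
#' @param run_dir Directory containing `summary.json`.
#' @return Invisibly, the report data frame.
#' @export
run_report <- function(run_dir) {
  sp <- file.path(run_dir, "summary.json")
  if (!file.exists(sp)) {
    stop("no summary.json in ", run_dir, " (run the compare step first)",
         call. = FALSE)
  }
  s <- jsonlite::read_json(sp, simplifyVector = TRUE)
  counts <- unlist(s$counts)
  n_total <- s$n_total
  if (is.null(n_total) || n_total == 0) {
    rep_df <- data.frame(category = "total", count = 0, percent = "undefined",
                         stringsAsFactors = FALSE)
  } else {
    # recompute from counts so the report can never drift from the summary
    pct <- summarize_comparison(counts[["dmr_a"]], counts[["dmr_b"]], n_total)
    rep_df <- data.frame(
      category = c(paste0("DMR_", s$cell_type_a), paste0("DMR_", s$cell_type_b),
                   "CMR", "total"),
      count = c(counts[["dmr_a"]], counts[["dmr_b"]], counts[["cmr"]], n_total),
      percent = c(fmt_pct(pct), "100%"),
      stringsAsFactors = FALSE)
  }
  write_tsv(rep_df, file.path(run_dir, "report.tsv"))
  lines <- c(sprintf("Methylated-region comparison: %s vs %s",
                     s$cell_type_a, s$cell_type_b),
             sprintf("  %-24s %8s  %s", rep_df$category, rep_df$count,
                     rep_df$percent))
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(rep_df)
}
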