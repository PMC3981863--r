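#' Construct and validate a gene model
#'
#' @param genes Data frame: `name`, `chrom`, `strand` (`+`/`-`), `tx_start`,
#'   `tx_end` (0-based half-open transcript span).
#' @param exons Data frame: `gene`, `chrom`, `start`, `end`; every exon must
#'   lie within its gene's transcript span and exons of a gene must not
#'   overlap each other.
#' @return A `gene_model` object.
#' @export
gene_model <- function(genes, exons) {
  stopifnot(all(c("name", "chrom", "strand", "tx_start", "tx_end") %in% names(genes)),
            all(c("gene", "chrom", "start", "end") %in% names(exons)))
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("gene %s has unknown strand symbol '%s'",
                 genes$name[bad[1]], genes$strand[bad[1]]), call. = FALSE)
  }
  if (any(genes$tx_start >= genes$tx_end)) {
    stop("gene with tx_start >= tx_end", call. = FALSE)
  }
  if (nrow(exons) > 0) {
    m <- match(exons$gene, genes$name)
    if (anyNA(m)) stop("exon references unknown gene", call. = FALSE)
    if (any(exons$start < genes$tx_start[m] | exons$end > genes$tx_end[m])) {
      stop("exon outside its gene's transcript span", call. = FALSE)
    }
    for (g in unique(exons$gene)) {
      e <- exons[exons$gene == g, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("overlapping exons within gene ", g, call. = FALSE)
      }
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Read a refFlat-style gene table
#'
#' Accepts either the compact 7-column form (geneName, chrom, strand,
#' txStart, txEnd, exonStarts, exonEnds — the last two comma-separated) or
#' the 11-column UCSC refFlat layout. Coordinates are 0-based half-open.
#'
#' @param path Path to a tab-separated file without header.
#' @return A `gene_model`.
#' @export
read_refflat <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) >= 11) {
    cols <- list(name = 1, chrom = 3, strand = 4, tx_start = 5, tx_end = 6,
                 ex_s = 10, ex_e = 11)
  } else if (ncol(tab) >= 7) {
    cols <- list(name = 1, chrom = 2, strand = 3, tx_start = 4, tx_end = 5,
                 ex_s = 6, ex_e = 7)
  } else {
    stop("gene table needs 7 (compact) or 11 (refFlat) columns", call. = FALSE)
  }
  genes <- data.frame(name = as.character(tab[[cols$name]]),
                      chrom = as.character(tab[[cols$chrom]]),
                      strand = as.character(tab[[cols$strand]]),
                      tx_start = as.integer(tab[[cols$tx_start]]),
                      tx_end = as.integer(tab[[cols$tx_end]]),
                      stringsAsFactors = FALSE)
  split_csv <- function(x) lapply(strsplit(as.character(x), ","), as.integer)
  es <- split_csv(tab[[cols$ex_s]])
  ee <- split_csv(tab[[cols$ex_e]])
  exons <- data.frame(
    gene = rep(genes$name, lengths(es)),
    chrom = rep(genes$chrom, lengths(es)),
    start = unlist(es), end = unlist(ee),
    stringsAsFactors = FALSE)
  gene_model(genes, exons)
}

#' Read a BED12 gene table
#'
#' Blocks (exons) are taken from blockSizes/blockStarts relative to the
#' record start, per the BED12 convention.
#'
#' @param path Path to a BED12 file.
#' @return A `gene_model`.
#' @export
read_bed12_genes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 12) stop("BED12 needs 12 columns", call. = FALSE)
  genes <- data.frame(name = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      strand = as.character(tab[[6]]),
                      tx_start = as.integer(tab[[2]]),
                      tx_end = as.integer(tab[[3]]),
                      stringsAsFactors = FALSE)
  sizes <- lapply(strsplit(as.character(tab[[11]]), ","), as.integer)
  offs <- lapply(strsplit(as.character(tab[[12]]), ","), as.integer)
  exons <- data.frame(
    gene = rep(genes$name, lengths(sizes)),
    chrom = rep(genes$chrom, lengths(sizes)),
    start = rep(genes$tx_start, lengths(offs)) + unlist(offs),
    stringsAsFactors = FALSE)
  exons$end <- exons$start + unlist(sizes)
  gene_model(genes, exons)
}

feature_granges <- function(model, promoter_up, promoter_down) {
  g <- model$genes
  tss_plus <- g$strand == "+"
  # promoter window around the TSS, strand-aware; clipped at position 0
  prom_start <- ifelse(tss_plus, g$tx_start - promoter_up,
                       g$tx_end - promoter_down)
  prom_end <- ifelse(tss_plus, g$tx_start + promoter_down,
                     g$tx_end + promoter_up)
  prom_start <- pmax(prom_start, 0L)
  prom <- GRanges(g$chrom, IRanges(prom_start + 1L, prom_end))
  prom$gene <- g$name
  ex <- if (nrow(model$exons) > 0) {
    e <- GRanges(model$exons$chrom,
                 IRanges(model$exons$start + 1L, model$exons$end))
    e$gene <- model$exons$gene
    e
  } else {
    e <- GRanges(); e$gene <- character(0); e
  }
  body <- GRanges(g$chrom, IRanges(g$tx_start + 1L, g$tx_end))
  body$gene <- g$name
  # introns: per-gene body minus exons
  intr_list <- lapply(seq_len(nrow(g)), function(i) {
    ei <- ex[ex$gene == g$name[i]]
    di <- GenomicRanges::setdiff(body[i], ei)
    if (length(di)) di$gene <- g$name[i] else di$gene <- character(0)
    di
  })
  intr <- if (length(intr_list)) {
    do.call(c, intr_list)
  } else {
    i0 <- GRanges(); i0$gene <- character(0); i0
  }
  list(promoter = prom, exon = ex, intron = intr)
}

# winning gene for each query region: largest base overlap, ties by name
pick_gene <- function(gq, feat, min_overlap = 1L) {
  if (length(gq) == 0 || length(feat) == 0) {
    return(rep(NA_character_, length(gq)))
  }
  h <- harmonize(gq, feat)
  hits <- GenomicRanges::findOverlaps(h$a, h$b,
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0) return(rep(NA_character_, length(gq)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(h$a[qi], h$b[si]))
  gene <- h$b$gene[si]
  key <- paste(qi, gene, sep = "\r")
  per_gene <- tapply(ov, key, sum)
  kq <- as.integer(sub("\r.*", "", names(per_gene)))
  kg <- sub(".*\r", "", names(per_gene))
  out <- rep(NA_character_, length(gq))
  ord <- order(kq, -as.numeric(per_gene), kg)
  for (k in ord) if (is.na(out[kq[k]])) out[kq[k]] <- kg[k]
  out
}

#' Annotate regions against a gene model
#'
#' Assigns each region exactly one category with precedence
#' promoter > exon > intron > intergenic. The promoter window is
#' TSS-`promoter_up` .. TSS+`promoter_down`, computed strand-aware (TSS is
#' `tx_start` for `+` genes and `tx_end` for `-` genes). When a region
#' overlaps several genes within its winning category, the gene with the
#' largest base overlap is reported, ties broken by lexicographic gene name.
#'
#' @param regions A `region_set`, `consensus_set`, or interval data frame.
#' @param model A `gene_model`.
#' @param promoter_up,promoter_down Promoter window extent in bp upstream /
#'   downstream of the TSS (defaults 2000 / 500).
#' @return A list: `annotations` (data frame `chrom`, `start`, `end`,
#'   `category`, `gene`; `gene` is empty iff intergenic) and `counts`
#'   (named integer vector over the four categories, summing to the number
#'   of regions).
#' @export
annotate_regions <- function(regions, model, promoter_up = 2000L,
                             promoter_down = 500L) {
  stopifnot(inherits(model, "gene_model"))
  df <- intervals_of(regions)
  feats <- feature_granges(model, promoter_up, promoter_down)
  gq <- as_granges(df)
  category <- rep("intergenic", nrow(df))
  gene <- rep("", nrow(df))
  for (cat_name in c("promoter", "exon", "intron")) {
    todo <- category == "intergenic"
    if (!any(todo)) break
    g <- pick_gene(gq[todo], feats[[cat_name]])
    hitidx <- which(todo)[!is.na(g)]
    category[hitidx] <- cat_name
    gene[hitidx] <- g[!is.na(g)]
  }
  counts <- table(factor(category,
                         levels = c("promoter", "exon", "intron", "intergenic")))
  ann <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    category = category, gene = gene,
                    stringsAsFactors = FALSE)
  list(annotations = ann,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
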