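#' Build a feature model from a GTF annotation
#'
#' Loads exon records from a GTF file into a `GRanges` keyed by `gene_id`,
#' the overlap structure used for strand-specific union-mode read counting.
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying a
#'   `gene_id` attribute.
#' @return A `GRanges` of exons with a `gene_id` metadata column.
#' @export
feature_model <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("feature_model: GTF exons must carry a gene_id attribute")
  }
  if (any(BiocGenerics::start(gr) > BiocGenerics::end(gr))) {
    stop("feature_model: malformed exon interval (start > end)")
  }
  gr
}

#' Assign aligned reads to genes with union semantics
#'
#' A read is assigned to a gene iff exactly one gene has an exon overlapping
#' any aligned base on the same strand (the 3'-tag protocol is
#' strand-specific). Zero overlapping genes gives `no_feature`; more than
#' one gives `ambiguous` — ties are never broken heuristically.
#'
#' @param alignments A `GAlignments` object.
#' @param model Exon `GRanges` from [feature_model()].
#' @return Character vector per read: a gene id, `"__ambiguous"`, or
#'   `"__no_feature"`.
#' @export
assign_read_to_feature <- function(alignments, model) {
  blocks <- GenomicAlignments::grglist(alignments)
  ov <- GenomicRanges::findOverlaps(blocks, model, ignore.strand = FALSE)
  hit_gene <- model$gene_id[S4Vectors::subjectHits(ov)]
  per_read <- split(hit_gene, factor(S4Vectors::queryHits(ov),
                                     levels = seq_along(alignments)))
  vapply(per_read, function(g) {
    u <- unique(g)
    if (length(u) == 0L) "__no_feature"
    else if (length(u) == 1L) u
    else "__ambiguous"
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse reads sharing the same UMI within a cell and gene
#'
#' Reads with identical (cell, gene, UMI) derive from one captured molecule
#' and contribute a single count; UMIs are compared by exact sequence only.
#'
#' @param assignments data.frame with columns `cell`, `gene`, `umi`.
#' @return data.frame with columns `cell`, `gene`, `umi_count` (number of
#'   distinct UMIs).
#' @export
collapse_umis <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(cell = character(0), gene = character(0),
                      umi_count = integer(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(assignments[, c("cell", "gene", "umi")])
  res <- dt[, list(umi_count = data.table::uniqueN(umi)),
            by = c("cell", "gene")]
  as.data.frame(res)
}

#' Convert a distinct-UMI count into a molecule estimate
#'
#' Two molecules can draw the same UMI label, so the number of distinct
#' UMIs undershoots the number of molecules, increasingly so as the UMI
#' space fills. Under uniform random labelling of `m` molecules into `K`
#' labels, the expected number of distinct labels is
#' `K * (1 - (1 - 1/K)^m)`; inverting this occupancy relation gives the
#' binomial collision estimate
#' \deqn{\hat m = \log(1 - k/K) / \log(1 - 1/K).}
#' It maps 0 to 0 and 1 to exactly 1, is strictly increasing and convex in
#' `k`, and tends to `k` as `K` grows. At saturation (`k = K`) the formula
#' diverges; the value for `k = K - 1` is returned instead and the position
#' is flagged in the `"saturated"` attribute.
#'
#' @param k Distinct-UMI counts (vectorized), `0 <= k <= K`.
#' @param K UMI space size, `4^umi_length` (4096 for a 6-nt UMI).
#' @return Numeric molecule estimates with a logical `"saturated"`
#'   attribute marking capped entries.
#' @export
umis_to_molecules <- function(k, K) {
  if (K < 2) stop("umis_to_molecules: K must be >= 2")
  if (any(k < 0) || any(k > K)) {
    stop("umis_to_molecules: k must lie in [0, K]")
  }
  saturated <- k == K
  k_eff <- ifelse(saturated, K - 1, k)
  est <- log1p(-k_eff / K) / log1p(-1 / K)
  est[k_eff == 0] <- 0
  attr(est, "saturated") <- saturated
  est
}

# Read one SAM (or BAM) file into a GAlignments plus per-record flags/mapq,
# and the total record count (including unmapped).
read_alignment_file <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  total <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  list(alignments = aln, total = total)
}

#' Count UMI-deduplicated molecules per gene and cell from alignments
#'
#' For each per-cell SAM/BAM file: discards secondary/supplementary records
#' and records below the mapping-quality threshold (multi-mappers), assigns
#' the remaining reads to genes with strand-specific union semantics,
#' collapses reads sharing a UMI within each (cell, gene), and converts
#' distinct-UMI counts into molecule estimates with
#' [umis_to_molecules()]. Cell identity and UMI are taken from the
#' `:UMI:<seq>:CELL:<id>` query-name suffix written by [demultiplex_run()];
#' records lacking it are a contract violation and raise an error. Reads
#' whose UMI contains N are dropped and counted.
#'
#' @param alignment_files Character vector of per-cell SAM/BAM paths.
#' @param model Exon `GRanges` from [feature_model()].
#' @param umi_length UMI length in nt; the UMI space is `K = 4^umi_length`.
#' @param min_mapq Minimum mapping quality (default 10); lower-quality
#'   records are discarded as multi-mapped.
#' @param cells Optional cell ids to force as columns (defaults to the ids
#'   observed plus file basenames).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `umi_counts` (integer, distinct UMIs) and `molecule_estimates`
#'   (collision-corrected), genes as rows and cells as columns; the
#'   counting report and `K` sit in `metadata()`.
#' @export
count_run <- function(alignment_files, model, umi_length = 6L,
                      min_mapq = 10L, cells = NULL) {
  K <- 4^umi_length
  report <- c(assigned = 0L, ambiguous = 0L, no_feature = 0L, unmapped = 0L,
              discarded_multimapped = 0L, dropped_N_umi = 0L, total = 0L)
  rows <- list()
  file_cells <- sub("\\.(sam|bam)$", "", basename(alignment_files),
                    ignore.case = TRUE)
  for (fi in seq_along(alignment_files)) {
    f <- alignment_files[fi]
    rec <- read_alignment_file(f)
    aln <- rec$alignments
    report[["total"]] <- report[["total"]] + rec$total
    report[["unmapped"]] <- report[["unmapped"]] + rec$total - length(aln)
    if (length(aln) == 0L) next
    flag <- S4Vectors::mcols(aln)$flag
    secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
    lowq <- !secondary & S4Vectors::mcols(aln)$mapq < min_mapq
    report[["discarded_multimapped"]] <-
      report[["discarded_multimapped"]] + sum(secondary | lowq)
    aln <- aln[!(secondary | lowq)]
    if (length(aln) == 0L) next
    tags <- parse_read_tag(S4Vectors::mcols(aln)$qname)
    if (anyNA(tags$umi)) {
      bad <- which(is.na(tags$umi))[1]
      stop("count_run: record ", bad, " in ", f,
           " lacks the :UMI:<seq>:CELL:<id> query-name suffix; ",
           "alignments must come from reads demultiplexed by this package")
    }
    n_umi <- grepl("N", tags$umi, fixed = TRUE)
    report[["dropped_N_umi"]] <- report[["dropped_N_umi"]] + sum(n_umi)
    aln <- aln[!n_umi]
    tags <- tags[!n_umi, , drop = FALSE]
    if (length(aln) == 0L) next
    feat <- assign_read_to_feature(aln, model)
    report[["ambiguous"]] <- report[["ambiguous"]] + sum(feat == "__ambiguous")
    report[["no_feature"]] <- report[["no_feature"]] + sum(feat == "__no_feature")
    keep <- !(feat %in% c("__ambiguous", "__no_feature"))
    report[["assigned"]] <- report[["assigned"]] + sum(keep)
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = tags$cell[keep], gene = feat[keep], umi = tags$umi[keep],
        stringsAsFactors = FALSE)
    }
  }
  stopifnot(report[["assigned"]] + report[["ambiguous"]] +
              report[["no_feature"]] + report[["unmapped"]] +
              report[["discarded_multimapped"]] + report[["dropped_N_umi"]] ==
              report[["total"]])

  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(0), gene = character(0), umi = character(0))
  counts_long <- collapse_umis(assignments)
  genes <- sort(unique(model$gene_id))
  if (is.null(cells)) cells <- sort(unique(c(file_cells, counts_long$cell)))
  umi_counts <- matrix(0L, length(genes), length(cells),
                       dimnames = list(genes, cells))
  if (nrow(counts_long)) {
    umi_counts[cbind(match(counts_long$gene, genes),
                     match(counts_long$cell, cells))] <-
      as.integer(counts_long$umi_count)
  }
  mol <- umis_to_molecules(umi_counts, K)
  saturated <- matrix(attr(mol, "saturated"), nrow(umi_counts),
                      dimnames = dimnames(umi_counts))
  mol <- matrix(as.numeric(mol), nrow(umi_counts),
                dimnames = dimnames(umi_counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(umi_counts = umi_counts, molecule_estimates = mol),
    metadata = list(K = K, umi_length = as.integer(umi_length),
                    report = report, saturated = saturated))
}

#' Write the two count-matrix layers and the counting report as TSV
#'
#' Emits `umi_counts.tsv` and `molecules.tsv` (genes as rows, cells as
#' columns) plus `counting_report.tsv`, and optionally an MTX triplet of
#' the UMI layer.
#'
#' @param se `SummarizedExperiment` from [count_run()].
#' @param out_dir Output directory.
#' @param mtx Also write `umi_counts.mtx` (MatrixMarket) with row/column
#'   name sidecars.
#' @return Named vector of written paths, invisibly.
#' @export
write_count_matrix <- function(se, out_dir, mtx = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(umi_counts = file.path(out_dir, "umi_counts.tsv"),
             molecules = file.path(out_dir, "molecules.tsv"),
             report = file.path(out_dir, "counting_report.tsv"))
  write_matrix_tsv(SummarizedExperiment::assay(se, "umi_counts"),
                   paths[["umi_counts"]])
  write_matrix_tsv(SummarizedExperiment::assay(se, "molecule_estimates"),
                   paths[["molecules"]])
  rep <- S4Vectors::metadata(se)$report
  utils::write.table(data.frame(category = names(rep), reads = unname(rep)),
                     paths[["report"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (mtx) {
    m <- Matrix::Matrix(SummarizedExperiment::assay(se, "umi_counts"),
                        sparse = TRUE)
    paths <- c(paths, mtx = file.path(out_dir, "umi_counts.mtx"))
    Matrix::writeMM(m, paths[["mtx"]])
    writeLines(rownames(m), file.path(out_dir, "genes.tsv"))
    writeLines(colnames(m), file.path(out_dir, "cells.tsv"))
  }
  invisible(paths)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-cells TSV matrix written by [write_count_matrix()]
#' @param path TSV with a `gene` column then one column per cell.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
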