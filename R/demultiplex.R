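#' Paired-end read structure of a CEL-Seq2 run
#'
#' Read 1 carries the UMI and the cell barcode (UMI upstream of the barcode
#' by default, positions 1-12 of a 15-base R1); read 2 carries the cDNA.
#' Bases of R1 beyond `umi_length + barcode_length` are ignored.
#'
#' @param umi_length UMI length in nt (6 for CEL-Seq2; the original CEL-Seq
#'   used 5, hence it is configurable).
#' @param barcode_length Cell-barcode length in nt.
#' @param umi_first If `TRUE` (default) the UMI precedes the barcode in R1.
#' @return A `ReadStructure` list.
#' @export
read_structure <- function(umi_length = 6L, barcode_length = 6L,
                           umi_first = TRUE) {
  stopifnot(umi_length >= 0L, barcode_length >= 1L)
  structure(list(umi_length = as.integer(umi_length),
                 barcode_length = as.integer(barcode_length),
                 umi_first = isTRUE(umi_first),
                 r1_min_length = as.integer(umi_length + barcode_length)),
            class = "ReadStructure")
}

#' Extract the UMI and cell barcode from an R1 sequence
#'
#' @param r1_sequence Character vector of R1 sequences.
#' @param structure A [read_structure()].
#' @return A data.frame with columns `umi`, `barcode` and logical
#'   `too_short`; for too-short reads umi/barcode are `NA`.
#' @export
parse_r1 <- function(r1_sequence, structure = read_structure()) {
  n <- nchar(r1_sequence)
  too_short <- n < structure$r1_min_length
  if (structure$umi_first) {
    umi <- substr(r1_sequence, 1L, structure$umi_length)
    barcode <- substr(r1_sequence, structure$umi_length + 1L,
                      structure$r1_min_length)
  } else {
    barcode <- substr(r1_sequence, 1L, structure$barcode_length)
    umi <- substr(r1_sequence, structure$barcode_length + 1L,
                  structure$r1_min_length)
  }
  umi[too_short] <- NA_character_
  barcode[too_short] <- NA_character_
  data.frame(umi = umi, barcode = barcode, too_short = too_short,
             stringsAsFactors = FALSE)
}

#' Assign an observed barcode to a set member, exact match only
#'
#' A minimum-distance-2 code detects single substitutions but cannot
#' uniquely correct them, so matching is exact: anything not in the set
#' (including single-error mutants and sequences containing N) is
#' unassigned, never misassigned.
#'
#' @param observed Character vector of observed barcode sequences.
#' @param barcode_set A `BarcodeSet`, a named character vector
#'   (id -> sequence) as returned by [read_barcodes()], or a plain character
#'   vector.
#' @return Character vector of barcode ids, `NA` where unassigned.
#' @export
assign_barcode <- function(observed, barcode_set) {
  lut <- barcode_lookup(barcode_set)
  names(lut)[match(observed, lut)]
}

# Append the UMI and cell-barcode tags to a read id, before any whitespace,
# so that an aligner carrying the query name forward preserves them in SAM.
tag_read_id <- function(id, umi, barcode) {
  first <- sub("\\s.*$", "", id)
  rest <- ifelse(grepl("\\s", id), sub("^\\S+", "", id), "")
  paste0(first, ":UMI:", umi, ":CELL:", barcode, rest)
}

# Parse the :UMI:<seq>:CELL:<id> suffix back out of a query name.
parse_read_tag <- function(qname) {
  m <- regmatches(qname, regexec(":UMI:([ACGTN]+):CELL:([^:\\s]+)", qname))
  umi <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  cell <- vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_, "")
  data.frame(umi = umi, cell = cell, stringsAsFactors = FALSE)
}

#' Demultiplex a paired-end FASTQ run into per-cell files
#'
#' Splits R2 reads by the cell barcode read in R1, writing one FASTQ per
#' barcode into `out_dir`. The UMI (also read in R1) is attached to the R2
#' read identifier as a `:UMI:<seq>:CELL:<id>` suffix before the first
#' whitespace, so it survives alignment in the SAM query name. Matching is
#' exact (see [assign_barcode()]); reads whose R1 is shorter than
#' `umi_length + barcode_length` are excluded and counted. Reads with N in
#' the UMI are kept (the counter decides their fate) but tallied.
#'
#' @param r1_path,r2_path Paths to the synchronized R1/R2 FASTQ files
#'   (plain or gzipped).
#' @param barcode_set As in [assign_barcode()].
#' @param structure A [read_structure()].
#' @param out_dir Output directory; created if absent.
#' @return A `DemuxReport` list: `per_barcode` (named integer vector),
#'   `unassigned`, `too_short`, `umi_with_N`, `total`, `files` (named paths).
#' @export
read_fastq_safe <- function(path) {
  # ShortRead rejects a zero-record FASTQ; treat it as an empty run
  if (file.size(path) == 0) return(ShortRead::ShortReadQ())
  ShortRead::readFastq(path)
}

demultiplex_run <- function(r1_path, r2_path, barcode_set,
                            structure = read_structure(), out_dir) {
  r1 <- read_fastq_safe(r1_path)
  r2 <- read_fastq_safe(r2_path)
  if (length(r1) != length(r2)) {
    stop("demultiplex_run: R1 has ", length(r1), " reads but R2 has ",
         length(r2), " (truncated or mismatched files)")
  }
  lut <- barcode_lookup(barcode_set)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(file.path(out_dir, paste0(names(lut), ".fastq")),
                           names(lut))
  report <- list(per_barcode = stats::setNames(integer(length(lut)), names(lut)),
                 unassigned = 0L, too_short = 0L, umi_with_N = 0L,
                 total = length(r1), files = files)
  class(report) <- "DemuxReport"
  if (length(r1) == 0L) return(report)

  id1 <- sub("\\s.*$", "", as.character(ShortRead::id(r1)))
  id2full <- as.character(ShortRead::id(r2))
  id2 <- sub("\\s.*$", "", id2full)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop("demultiplex_run: R1/R2 ids desynchronized at pair ", bad[1],
         ": '", id1[bad[1]], "' vs '", id2[bad[1]], "'")
  }

  parsed <- parse_r1(as.character(ShortRead::sread(r1)), structure)
  report$too_short <- sum(parsed$too_short)
  cell <- assign_barcode(parsed$barcode, lut)
  cell[parsed$too_short] <- NA_character_
  assigned <- !is.na(cell)
  report$unassigned <- sum(!assigned) - report$too_short
  report$umi_with_N <- sum(assigned & grepl("N", parsed$umi, fixed = TRUE))

  tagged_id <- id2full
  tagged_id[assigned] <- tag_read_id(id2full[assigned], parsed$umi[assigned],
                                     cell[assigned])
  for (bc in names(lut)) {
    sel <- which(assigned & cell == bc)
    report$per_barcode[[bc]] <- length(sel)
    out <- ShortRead::ShortReadQ(
      sread = ShortRead::sread(r2)[sel],
      quality = Biostrings::quality(r2)[sel],
      id = Biostrings::BStringSet(tagged_id[sel]))
    if (file.exists(files[[bc]])) file.remove(files[[bc]])
    ShortRead::writeFastq(out, files[[bc]], compress = FALSE)
  }
  stopifnot(sum(report$per_barcode) + report$unassigned + report$too_short ==
              report$total)
  report
}

#' @export
print.DemuxReport <- function(x, ...) {
  cat(sprintf("DemuxReport: %d pairs; %d assigned across %d barcodes; %d unassigned; %d too short; %d with N in UMI\n",
              x$total, sum(x$per_barcode), length(x$per_barcode),
              x$unassigned, x$too_short, x$umi_with_N))
  invisible(x)
}

#' Write a demultiplexing report as TSV
#' @param report A `DemuxReport`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_demux_report <- function(report, path) {
  tab <- data.frame(
    category = c(names(report$per_barcode), "unassigned", "too_short", "total"),
    reads = c(unname(report$per_barcode), report$unassigned,
              report$too_short, report$total))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subsample reads from a FASTQ file without replacement
#'
#' Draws exactly `min(n, total)` reads uniformly without replacement,
#' preserving input order, deterministically for a fixed seed. Used to
#' control for sequencing depth when comparing libraries (e.g. equalizing
#' samples at 300,000 reads).
#'
#' @param fastq_path Input FASTQ (plain or gzipped).
#' @param n Number of reads to keep.
#' @param seed Integer seed.
#' @param out_path Output FASTQ path (plain text).
#' @return `out_path`, invisibly.
#' @export
subsample_reads <- function(fastq_path, n, seed, out_path) {
  stopifnot(n >= 0)
  reads <- read_fastq_safe(fastq_path)
  k <- min(n, length(reads))
  idx <- withr::with_seed(seed, sort(sample.int(length(reads), k)))
  if (file.exists(out_path)) file.remove(out_path)
  ShortRead::writeFastq(reads[idx], out_path, compress = FALSE)
  invisible(out_path)
}
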