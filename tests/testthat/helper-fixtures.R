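# Shared fixture builders; everything is generated in code at test time.

# Minimal SAM writer for hand-specified records. `records` is a data.frame
# with columns qname, flag, pos, cigar, seq (rname fixed to chrT).
write_test_sam <- function(path, records, chrom_len = 1000L) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:chrT\tLN:", chrom_len))
  lines <- if (nrow(records)) {
    mapq <- if ("mapq" %in% names(records)) records$mapq else 255L
    paste(records$qname, records$flag, "chrT", records$pos, mapq,
          records$cigar, "*", 0L, 0L, records$seq,
          strrep("I", nchar(records$seq)), sep = "\t")
  } else character(0)
  writeLines(c(header, lines), path)
  path
}

# Two-gene GTF on chrT: GENE_A at 101-300 (+), GENE_B at 401-600 (+),
# plus GENE_C at 561-700 overlapping GENE_B's tail, and GENE_D at
# 801-900 on the minus strand.
write_test_gtf <- function(path) {
  row <- function(start, end, strand, gid) {
    paste("chrT", "test", "exon", start, end, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid),
          sep = "\t")
  }
  writeLines(c(row(101, 300, "+", "GENE_A"),
               row(401, 600, "+", "GENE_B"),
               row(561, 700, "+", "GENE_C"),
               row(801, 900, "-", "GENE_D")), path)
  path
}

# Plain four-line-per-read FASTQ writer for hand-built read pairs.
write_test_fastq <- function(path, ids, seqs) {
  if (length(ids) == 0L) {
    writeLines(character(0), path)
    return(path)
  }
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

# SAM query name carrying the demultiplex tag contract.
tagged_qname <- function(read, umi, cell) {
  paste0(read, ":UMI:", umi, ":CELL:", cell)
}
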