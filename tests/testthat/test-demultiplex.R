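test_that("parse_r1 slices UMI then barcode and flags too-short reads", {
  s <- read_structure(6, 6)
  p <- parse_r1(c("ACGTACCCGGTTAAA", "ACGTACCCGGTT", "ACGTA"), s)
  expect_identical(p$umi, c("ACGTAC", "ACGTAC", NA))
  expect_identical(p$barcode, c("CCGGTT", "CCGGTT", NA))
  expect_identical(p$too_short, c(FALSE, FALSE, TRUE))

  swapped <- parse_r1("CCGGTTACGTAC", read_structure(6, 6, umi_first = FALSE))
  expect_identical(swapped$barcode, "CCGGTT")
  expect_identical(swapped$umi, "ACGTAC")
})

test_that("assign_barcode is exact-only: members match, mutants and N go unassigned", {
  bs <- design_barcodes(6, 2, c(33, 67), "T", max_count = 8)
  lut <- stats::setNames(bs$barcodes, paste0("BC", 1:8))
  expect_identical(assign_barcode(bs$barcodes[3], lut), "BC3")
  mutant <- sub("^.", ifelse(substr(bs$barcodes[1], 1, 1) == "A", "C", "A"),
                bs$barcodes[1])
  expect_identical(assign_barcode(mutant, lut), NA_character_)
  expect_identical(assign_barcode("NNNNNN", lut), NA_character_)
})

make_pairs <- function(barcodes, umis_per_cell = 5L) {
  ids <- character(0); r1 <- character(0)
  for (ci in seq_along(barcodes)) {
    for (u in seq_len(umis_per_cell)) {
      ids <- c(ids, sprintf("rd%d_%d", ci, u))
      umi <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                   collapse = "")
      r1 <- c(r1, paste0(umi, barcodes[ci], "AAA"))
    }
  }
  list(ids = ids, r1 = r1,
       r2 = vapply(ids, function(i)
         paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE),
               collapse = ""), ""))
}

test_that("demultiplex_run splits error-free pairs into per-cell files with UMIs tagged", {
  withr::local_seed(11)
  bs <- design_barcodes(6, 2, c(33, 67), "T", max_count = 2)
  lut <- stats::setNames(bs$barcodes, c("BC1", "BC2"))
  pr <- make_pairs(lut)
  dir <- withr::local_tempdir()
  r1p <- write_test_fastq(file.path(dir, "R1.fastq"), pr$ids, pr$r1)
  r2p <- write_test_fastq(file.path(dir, "R2.fastq"), pr$ids, pr$r2)
  rep <- demultiplex_run(r1p, r2p, lut, read_structure(), file.path(dir, "out"))
  expect_identical(unname(rep$per_barcode), c(5L, 5L))
  expect_identical(rep$unassigned, 0L)
  expect_identical(rep$too_short, 0L)
  out1 <- ShortRead::readFastq(rep$files[["BC1"]])
  expect_length(out1, 5L)
  ids <- as.character(ShortRead::id(out1))
  expect_true(all(grepl(":UMI:[ACGT]{6}:CELL:BC1$", ids)))
  # UMI in the tag equals the UMI in R1
  expect_identical(sub(":UMI:([ACGT]{6}).*", "\\1", sub(".*?(:UMI:)", ":UMI:", ids)),
                   substr(pr$r1[1:5], 1, 6))
  # conservation
  expect_identical(sum(rep$per_barcode) + rep$unassigned + rep$too_short,
                   rep$total)
})

test_that("single substitutions in the barcode are never misassigned, only unassigned", {
  withr::local_seed(12)
  bs <- design_barcodes(6, 2, c(33, 67), "T", max_count = 4)
  lut <- stats::setNames(bs$barcodes, paste0("BC", 1:4))
  pr <- make_pairs(lut, umis_per_cell = 3L)
  # corrupt every barcode with exactly one substitution
  r1_bad <- vapply(pr$r1, function(s) {
    p <- sample(7:12, 1)
    b <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    s
  }, "", USE.NAMES = FALSE)
  dir <- withr::local_tempdir()
  r1p <- write_test_fastq(file.path(dir, "R1.fastq"), pr$ids, r1_bad)
  r2p <- write_test_fastq(file.path(dir, "R2.fastq"), pr$ids, pr$r2)
  rep <- demultiplex_run(r1p, r2p, lut, read_structure(), file.path(dir, "out"))
  expect_identical(sum(rep$per_barcode), 0L)
  expect_identical(rep$unassigned, rep$total)
})

test_that("demultiplex_run handles empty input and detects desynchronized pairs", {
  dir <- withr::local_tempdir()
  e1 <- write_test_fastq(file.path(dir, "e1.fastq"), character(0), character(0))
  e2 <- write_test_fastq(file.path(dir, "e2.fastq"), character(0), character(0))
  lut <- c(BC1 = "ACACAC")
  rep <- demultiplex_run(e1, e2, lut, read_structure(), file.path(dir, "out"))
  expect_identical(rep$total, 0L)

  a <- write_test_fastq(file.path(dir, "a.fastq"), c("r1", "r2"),
                        c(strrep("A", 15), strrep("A", 15)))
  b <- write_test_fastq(file.path(dir, "b.fastq"), c("r1", "rX"),
                        c(strrep("C", 36), strrep("C", 36)))
  expect_error(demultiplex_run(a, b, lut, read_structure(),
                               file.path(dir, "out2")),
               "desynchronized at pair 2")
})

test_that("subsample_reads is deterministic, exact-sized and order-preserving", {
  withr::local_seed(13)
  dir <- withr::local_tempdir()
  ids <- sprintf("r%03d", 1:100)
  seqs <- vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
  fq <- write_test_fastq(file.path(dir, "in.fastq"), ids, seqs)

  o1 <- file.path(dir, "s1.fastq"); o2 <- file.path(dir, "s2.fastq")
  subsample_reads(fq, 30, seed = 5, o1)
  subsample_reads(fq, 30, seed = 5, o2)
  expect_identical(readLines(o1), readLines(o2))
  kept <- as.character(ShortRead::id(ShortRead::readFastq(o1)))
  expect_length(kept, 30L)
  expect_identical(kept, sort(kept))  # input order = lexicographic here

  all_out <- file.path(dir, "all.fastq")
  subsample_reads(fq, 100, seed = 1, all_out)
  expect_identical(sort(as.character(ShortRead::id(ShortRead::readFastq(all_out)))),
                   sort(ids))
  none_out <- file.path(dir, "none.fastq")
  subsample_reads(fq, 0, seed = 1, none_out)
  expect_length(ShortRead::readFastq(none_out), 0L)
})
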