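test_that("umis_to_molecules matches its closed form at anchor points and saturates gracefully", {
  expect_identical(as.numeric(umis_to_molecules(0, 4096)), 0)
  expect_identical(as.numeric(umis_to_molecules(1, 4096)), 1)
  # frozen from exact-rational evaluation of ln(1/2)/ln(4095/4096)
  expect_equal(as.numeric(umis_to_molecules(2048, 4096)), 2838.78426388,
               tolerance = 1e-9)
  sat <- umis_to_molecules(4096, 4096)
  expect_true(attr(sat, "saturated"))
  expect_equal(as.numeric(sat), as.numeric(umis_to_molecules(4095, 4096)))
  expect_error(umis_to_molecules(5, 4), "k must lie")
  expect_error(umis_to_molecules(1, 1), "K must be")
})

test_that("collision correction is increasing, convex, and never below the raw count", {
  K <- 4096
  k <- 1:(K - 1)
  m <- as.numeric(umis_to_molecules(k, K))
  expect_true(all(diff(m) > 0))          # strictly increasing
  expect_true(all(diff(diff(m)) > 0))    # convex
  expect_true(all(m >= k))               # correction never shrinks
  # K -> infinity limit: estimate tends to k
  expect_equal(as.numeric(umis_to_molecules(100, 1e9)), 100, tolerance = 1e-5)
})

test_that("correction recovers the number of molecules behind observed distinct labels", {
  withr::local_seed(21)
  K <- 4096
  reps <- 200
  for (m in c(10, 500)) {
    distinct <- vapply(seq_len(reps), function(i) {
      length(unique(sample.int(K, m, replace = TRUE)))
    }, integer(1))
    est <- as.numeric(umis_to_molecules(distinct, K))
    se <- stats::sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - m), 2 * se + 1e-9)
  }
})

test_that("collapse_umis counts distinct UMIs per cell and gene without cross-gene collapse", {
  a <- data.frame(cell = "c1", gene = "g1",
                  umi = c("AAAAAA", "AAAAAA", "AAAAAA", "CCCCCC", "CCCCCC"))
  expect_identical(collapse_umis(a)$umi_count, 2L)

  b <- data.frame(cell = "c1", gene = c("g1", "g2"), umi = "AAAAAA")
  res <- collapse_umis(b)
  expect_identical(res$umi_count, c(1L, 1L))

  empty <- collapse_umis(data.frame(cell = character(0), gene = character(0),
                                    umi = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("union-mode assignment respects strand and discards ambiguity", {
  dir <- withr::local_tempdir()
  model <- feature_model(write_test_gtf(file.path(dir, "genes.gtf")))
  aln <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle("chrT", 4),
    pos = c(150L,   # inside GENE_A, + strand
            570L,   # overlaps GENE_B and GENE_C
            150L,   # inside GENE_A but on - strand
            820L),  # inside GENE_D (- gene) but read on + strand
    cigar = rep("36M", 4),
    strand = S4Vectors::Rle(GenomicRanges::strand(c("+", "+", "-", "+"))))
  feat <- assign_read_to_feature(aln, model)
  expect_identical(feat, c("GENE_A", "__ambiguous", "__no_feature",
                           "__no_feature"))
  # reverse-strand read on the reverse-strand gene is assigned
  rev <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle("chrT", 1), pos = 820L, cigar = "36M",
    strand = S4Vectors::Rle(GenomicRanges::strand("-")))
  expect_identical(assign_read_to_feature(rev, model), "GENE_D")
})

hand_sam <- function(dir, cell, entries, name = cell) {
  df <- do.call(rbind, lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    data.frame(qname = tagged_qname(paste0("r", name, i), e$umi, cell),
               flag = if (is.null(e$flag)) 0L else e$flag,
               pos = e$pos, cigar = "36M", seq = strrep("A", 36),
               mapq = if (is.null(e$mapq)) 255L else e$mapq)
  }))
  write_test_sam(file.path(dir, paste0(name, ".sam")), df)
}

test_that("count_run reproduces hand-computed distinct-UMI counts and a conserved report", {
  dir <- withr::local_tempdir()
  gtf <- write_test_gtf(file.path(dir, "genes.gtf"))
  model <- feature_model(gtf)
  # cell1: GENE_A gets UMIs {AAAAAA x2, CCCCCC}; cell2: GENE_A gets {GGGGGG}
  # plus one low-mapq record, one ambiguous, one N-UMI, one intergenic
  s1 <- hand_sam(dir, "cell1", list(
    list(umi = "AAAAAA", pos = 150),
    list(umi = "AAAAAA", pos = 160),
    list(umi = "CCCCCC", pos = 150),
    list(umi = "ACGTAC", pos = 150, mapq = 0),   # discarded multimapped
    list(umi = "ACGTAC", pos = 570),             # ambiguous (B and C)
    list(umi = "ACGNAC", pos = 150),             # dropped N UMI
    list(umi = "ACGTAC", pos = 720)))            # no feature
  s2 <- hand_sam(dir, "cell2", list(list(umi = "GGGGGG", pos = 150)))
  se <- count_run(c(s1, s2), model, umi_length = 6)
  m <- SummarizedExperiment::assay(se, "umi_counts")
  expect_identical(m["GENE_A", "cell1"], 2L)
  expect_identical(m["GENE_A", "cell2"], 1L)
  expect_identical(sum(m), 3L)
  rep <- S4Vectors::metadata(se)$report
  expect_identical(unname(rep[["assigned"]]), 4L)
  expect_identical(unname(rep[["ambiguous"]]), 1L)
  expect_identical(unname(rep[["no_feature"]]), 1L)
  expect_identical(unname(rep[["discarded_multimapped"]]), 1L)
  expect_identical(unname(rep[["dropped_N_umi"]]), 1L)
  expect_identical(sum(rep[setdiff(names(rep), "total")]), rep[["total"]])
  # molecule estimates: zero iff umi count zero, never below the raw count
  mol <- SummarizedExperiment::assay(se, "molecule_estimates")
  expect_identical(mol == 0, m == 0L)
  expect_true(all(mol >= m - 1e-9))
})

test_that("count_run is invariant under permutation of input records", {
  withr::local_seed(22)
  dir <- withr::local_tempdir()
  model <- feature_model(write_test_gtf(file.path(dir, "genes.gtf")))
  entries <- lapply(1:20, function(i) {
    list(umi = paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                     collapse = ""),
         pos = sample(c(150L, 420L), 1))
  })
  sA <- hand_sam(dir, "cellX", entries, name = "ordA")
  sB <- hand_sam(dir, "cellX", rev(entries), name = "ordB")
  mA <- SummarizedExperiment::assay(count_run(sA, model, cells = "cellX"),
                                    "umi_counts")
  mB <- SummarizedExperiment::assay(count_run(sB, model, cells = "cellX"),
                                    "umi_counts")
  expect_identical(mA, mB)
})

test_that("records without the UMI/cell query-name tag are a hard error", {
  dir <- withr::local_tempdir()
  model <- feature_model(write_test_gtf(file.path(dir, "genes.gtf")))
  sam <- write_test_sam(file.path(dir, "bad.sam"), data.frame(
    qname = "plainread", flag = 0L, pos = 150L, cigar = "36M",
    seq = strrep("A", 36), mapq = 255L))
  expect_error(count_run(sam, model), "query-name suffix")
})

test_that("count matrices round-trip through TSV and MTX export", {
  dir <- withr::local_tempdir()
  model <- feature_model(write_test_gtf(file.path(dir, "genes.gtf")))
  sam <- hand_sam(dir, "cell1", list(list(umi = "AAAAAA", pos = 150)))
  se <- count_run(sam, model)
  paths <- write_count_matrix(se, file.path(dir, "counts"), mtx = TRUE)
  back <- read_matrix_tsv(paths[["umi_counts"]])
  expect_equal(back, SummarizedExperiment::assay(se, "umi_counts") * 1.0)
  mm <- Matrix::readMM(paths[["mtx"]])
  expect_equal(sum(mm), sum(back))
})
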