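#' Configuration for a synthetic CEL-Seq2 run
#'
#' The defaults mirror the protocol's sequencing geometry: a 6-nt UMI
#' upstream of a 6-nt cell barcode in a 15-base read 1, a 36-base read 2
#' from the gene's 3' end, 92 spike-in species, and a capture efficiency of
#' 0.2 (the order measured for the protocol on spike-ins). Per-gene mean
#' molecule counts lie on a log-uniform grid; genes listed in
#' `noise_genes` receive extra-Poisson noise via a gamma-Poisson draw with
#' variance inflated `noise_factor`-fold (so their CV^2 is `noise_factor`
#' times the Poisson baseline).
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of endogenous genes.
#' @param n_spikeins Number of spike-in species (92-species ERCC mix).
#' @param gene_mean_range Range of per-gene mean molecules per cell
#'   (log-uniform grid across genes).
#' @param spike_range Range of expected spike-in molecules per cell
#'   (log-uniform ladder across species).
#' @param noise_genes Integer indices of genes given extra-Poisson noise.
#' @param noise_factor Variance inflation factor for those genes (> 1).
#' @param capture_efficiency Probability each molecule is captured
#'   (Bernoulli per molecule).
#' @param umi_length,barcode_length UMI / cell-barcode lengths in nt.
#' @param error_rate_barcode,error_rate_umi Per-base substitution
#'   probabilities applied to the respective R1 segment.
#' @param read_length_r2 R2 (cDNA) read length in nt.
#' @param r1_length Total R1 length in nt (padding after UMI+barcode).
#' @param gene_length Length of each synthetic single-exon gene in nt.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_cells = 20L, n_genes = 100L, n_spikeins = 92L,
                       gene_mean_range = c(0.5, 100),
                       spike_range = c(0.1, 5000),
                       noise_genes = integer(0), noise_factor = 1,
                       capture_efficiency = 0.2,
                       umi_length = 6L, barcode_length = 6L,
                       error_rate_barcode = 0, error_rate_umi = 0,
                       read_length_r2 = 36L, r1_length = 15L,
                       gene_length = 200L, seed = 1L) {
  stopifnot(capture_efficiency > 0, capture_efficiency <= 1,
            error_rate_barcode >= 0, error_rate_barcode <= 1,
            error_rate_umi >= 0, error_rate_umi <= 1,
            n_cells >= 1L, n_genes >= 1L, n_spikeins >= 0L,
            noise_factor >= 1)
  if (gene_length < read_length_r2) {
    stop("sim_config: gene_length must be >= read_length_r2")
  }
  if (r1_length < umi_length + barcode_length) {
    stop("sim_config: r1_length must cover UMI + barcode")
  }
  structure(as.list(environment()), class = "SimConfig")
}

#' Log-uniform ladder of expected spike-in molecule abundances
#'
#' Mimics the dynamic range of the 92-species ERCC mix: `n_species`
#' log-evenly spaced abundances from `min_molecules` to `max_molecules`.
#'
#' @param n_species Number of species (>= 2).
#' @param min_molecules,max_molecules Endpoints, molecules per cell.
#' @return data.frame with `spikein_id`, `expected_molecules`.
#' @export
ercc_ladder <- function(n_species = 92L, min_molecules = 0.1,
                        max_molecules = 5000) {
  stopifnot(n_species >= 2L, min_molecules > 0,
            min_molecules < max_molecules)
  data.frame(
    spikein_id = sprintf("ERCC-%05d", seq_len(n_species)),
    expected_molecules = 10^seq(log10(min_molecules), log10(max_molecules),
                                length.out = n_species),
    stringsAsFactors = FALSE)
}

# Draw true molecule counts: Poisson, or gamma-Poisson with variance
# inflated by `factor` (size = mu / (factor - 1) gives var = factor * mu).
draw_true_counts <- function(n, mu, factor = 1) {
  if (factor <= 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = mu / (factor - 1), mu = mu)
  }
}

#' Simulate ground-truth molecule counts (no reads)
#'
#' Draws, per cell and feature, true molecule counts (Poisson around each
#' feature's mean; gamma-Poisson for noise genes), Bernoulli capture at
#' `capture_efficiency`, and a uniform random UMI for every captured
#' molecule — the quantities every downstream statistic is checked
#' against. Feature rows are the `n_genes` endogenous genes followed by the
#' spike-in species.
#'
#' @param config A [sim_config()].
#' @return A `SimTruth` list: matrices `true`, `captured`, `umi_distinct`
#'   (features x cells), `umis` (nested list of UMI label vectors),
#'   `gene_means`, `spike_expected` (data.frame), `barcodes` (named
#'   vector id -> sequence), `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    bs <- design_barcodes(config$barcode_length, 2L, c(33, 67), "T",
                          max_count = config$n_cells)
    if (length(bs) < config$n_cells) {
      stop("simulate_counts: barcode design yields only ", length(bs),
           " barcodes for ", config$n_cells, " cells")
    }
    barcodes <- barcode_lookup(bs, prefix = "CELL")
    gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
    gene_means <- 10^seq(log10(config$gene_mean_range[1]),
                         log10(config$gene_mean_range[2]),
                         length.out = config$n_genes)
    names(gene_means) <- gene_ids
    spikes <- if (config$n_spikeins >= 2L) {
      ercc_ladder(config$n_spikeins, config$spike_range[1],
                  config$spike_range[2])
    } else {
      data.frame(spikein_id = character(0), expected_molecules = numeric(0))
    }
    feat_ids <- c(gene_ids, spikes$spikein_id)
    feat_means <- c(gene_means, stats::setNames(spikes$expected_molecules,
                                                spikes$spikein_id))
    noise <- rep(1, length(feat_ids))
    noise[config$noise_genes] <- config$noise_factor

    K <- 4^config$umi_length
    n_feat <- length(feat_ids)
    true <- matrix(0L, n_feat, config$n_cells,
                   dimnames = list(feat_ids, names(barcodes)))
    for (i in seq_len(n_feat)) {
      true[i, ] <- draw_true_counts(config$n_cells, feat_means[i], noise[i])
    }
    captured <- matrix(
      stats::rbinom(length(true), true, config$capture_efficiency),
      n_feat, dimnames = dimnames(true))
    umis <- lapply(seq_len(config$n_cells), function(ci) {
      lapply(seq_len(n_feat), function(fi) {
        m <- captured[fi, ci]
        if (m > 0) sample.int(K, m, replace = TRUE) else integer(0)
      })
    })
    umi_distinct <- matrix(0L, n_feat, config$n_cells,
                           dimnames = dimnames(true))
    for (ci in seq_len(config$n_cells)) {
      umi_distinct[, ci] <- vapply(umis[[ci]],
                                   function(u) length(unique(u)), integer(1))
    }
    structure(list(true = true, captured = captured,
                   umi_distinct = umi_distinct, umis = umis,
                   gene_means = gene_means, spike_expected = spikes,
                   barcodes = barcodes, config = config),
              class = "SimTruth")
  })
}

# Integer UMI label (1..4^len) -> DNA string of given length.
umi_int_to_seq <- function(x, len) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", length(x), len)
  x <- x - 1L
  for (p in len:1) {
    out[, p] <- bases[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(out, 1L, paste0, collapse = "")
}

# Per-base substitution errors at the given rate (never to the same base).
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  hit <- matrix(stats::runif(length(mat)) < rate, nrow(mat))
  if (any(hit)) {
    idx <- which(hit)
    orig <- mat[idx]
    mat[idx] <- vapply(orig, function(b) sample(setdiff(bases, b), 1L), "")
  }
  apply(mat, 1L, paste0, collapse = "")
}

#' Simulate a full synthetic CEL-Seq2 run with ground truth
#'
#' Builds a synthetic reference of disjoint single-exon genes, draws
#' molecule counts and UMIs as in [simulate_counts()], and writes every
#' artifact a real run would have: reference FASTA, annotation GTF, paired
#' R1/R2 FASTQ (R1 = UMI + barcode + padding, with substitution errors at
#' the configured rates), one SAM per cell holding the error-free
#' alignment of each R2 read (so the counter is testable without an
#' external aligner; a genuine aligner can be substituted on the demu-
#' ltiplexed FASTQs), the expected-molecule sheet, and truth tables. Reads
#' come from a fixed-length window at each gene's 3' end, modelling the
#' protocol's strong 3' bias. Fully deterministic given `config$seed`.
#'
#' SAM query names carry the observed (post-error) UMI and the true cell
#' id, i.e. the alignments correspond to an error-free demultiplexing;
#' barcode-error behaviour is exercised through the FASTQ route.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory to write artifacts into (created).
#' @return A list with `truth` (the `SimTruth`) and `paths` (named:
#'   `reference`, `gtf`, `r1`, `r2`, `sam_dir`, `sam` vector,
#'   `spike_expected`, `true_molecules`, `captured_molecules`,
#'   `barcodes`).
#' @export
simulate_run <- function(config, out_dir) {
  stopifnot(inherits(config, "SimConfig"))
  truth <- simulate_counts(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sam_dir <- file.path(out_dir, "aligned")
  dir.create(sam_dir, showWarnings = FALSE)

  withr::with_seed(config$seed + 1L, {
    feat_ids <- rownames(truth$true)
    n_feat <- length(feat_ids)
    gap <- 100L
    starts <- (seq_len(n_feat) - 1L) * (config$gene_length + gap) + gap + 1L
    ends <- starts + config$gene_length - 1L
    chrom_len <- ends[n_feat] + gap
    ref_seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                     collapse = "")
    ref <- Biostrings::DNAStringSet(ref_seq)
    names(ref) <- "chrS"
    paths <- list(reference = file.path(out_dir, "reference.fa"),
                  gtf = file.path(out_dir, "genes.gtf"),
                  r1 = file.path(out_dir, "R1.fastq"),
                  r2 = file.path(out_dir, "R2.fastq"),
                  sam_dir = sam_dir,
                  spike_expected = file.path(out_dir, "expected_molecules.tsv"),
                  true_molecules = file.path(out_dir, "true_molecules.tsv"),
                  captured_molecules = file.path(out_dir, "captured_molecules.tsv"),
                  barcodes = file.path(out_dir, "barcodes.tsv"))
    Biostrings::writeXStringSet(ref, paths$reference)

    exons <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(starts, ends), strand = "+",
      type = "exon", gene_id = feat_ids,
      transcript_id = paste0(feat_ids, ".t1"))
    rtracklayer::export(exons, paths$gtf, format = "gtf")

    # one read per captured molecule, from the 3'-terminal window
    recs <- list()
    read_no <- 0L
    for (ci in seq_len(config$n_cells)) {
      cell_id <- names(truth$barcodes)[ci]
      for (fi in seq_len(n_feat)) {
        m <- truth$captured[fi, ci]
        if (m == 0L) next
        umi_seq <- umi_int_to_seq(truth$umis[[ci]][[fi]], config$umi_length)
        pos <- rep(ends[fi] - config$read_length_r2 + 1L, m)
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = paste0("simread", read_no + seq_len(m)),
          cell = cell_id, feature = feat_ids[fi], umi = umi_seq, pos = pos,
          stringsAsFactors = FALSE)
        read_no <- read_no + m
      }
    }
    reads <- if (length(recs)) do.call(rbind, recs) else
      data.frame(read_id = character(0), cell = character(0),
                 feature = character(0), umi = character(0),
                 pos = integer(0))

    r2_seq <- substring(ref_seq, reads$pos,
                        reads$pos + config$read_length_r2 - 1L)
    umi_obs <- mutate_bases(reads$umi, config$error_rate_umi)
    bc_obs <- mutate_bases(unname(truth$barcodes[reads$cell]),
                           config$error_rate_barcode)
    pad <- strrep("A", config$r1_length - config$umi_length -
                    config$barcode_length)
    r1_seq <- paste0(umi_obs, bc_obs, pad)

    write_fastq_plain(reads$read_id, r1_seq, paths$r1)
    write_fastq_plain(reads$read_id, r2_seq, paths$r2)

    # per-cell SAM with by-construction alignments
    header <- c("@HD\tVN:1.6\tSO:unknown",
                paste0("@SQ\tSN:chrS\tLN:", chrom_len))
    sam_paths <- character(0)
    for (ci in seq_len(config$n_cells)) {
      cell_id <- names(truth$barcodes)[ci]
      sel <- which(reads$cell == cell_id)
      qname <- paste0(reads$read_id[sel], ":UMI:", umi_obs[sel],
                      ":CELL:", cell_id)
      lines <- if (length(sel)) {
        paste(qname, 0L, "chrS", reads$pos[sel], 255L,
              paste0(config$read_length_r2, "M"), "*", 0L, 0L,
              r2_seq[sel], strrep("I", config$read_length_r2), sep = "\t")
      } else character(0)
      p <- file.path(sam_dir, paste0(cell_id, ".sam"))
      writeLines(c(header, lines), p)
      sam_paths <- c(sam_paths, p)
    }
    paths$sam <- sam_paths

    utils::write.table(truth$spike_expected, paths$spike_expected,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(truth$true, paths$true_molecules)
    write_matrix_tsv(truth$captured, paths$captured_molecules)
    write_barcodes(unname(truth$barcodes), paths$barcodes, prefix = "CELL")
    list(truth = truth, paths = paths)
  })
}

write_fastq_plain <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  out <- character(4L * length(ids))
  if (length(ids)) {
    out[seq(1, length(out), 4)] <- paste0("@", ids)
    out[seq(2, length(out), 4)] <- seqs
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}
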