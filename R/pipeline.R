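#' Assemble and validate a pipeline configuration
#'
#' Every referenced input must exist at validation time. Fields mirror the
#' stage options: demultiplexing geometry, counting mode, QC settings, and
#' an optional external-aligner command template (`align_cmd`, with
#' `{fastq}` and `{sam}` placeholders) run per demultiplexed cell; without
#' one, `sam_dir` must hold pre-made per-cell SAM/BAM files named
#' `<cell>.sam`.
#'
#' @param r1,r2 Paired FASTQ paths.
#' @param barcodes Barcode TSV (id <TAB> sequence).
#' @param gtf Gene annotation GTF.
#' @param out_dir Output directory.
#' @param sam_dir Directory of per-cell alignments (if no `align_cmd`).
#' @param align_cmd Optional shell command template.
#' @param spikeins Optional expected-molecule TSV for the efficiency fit.
#' @param umi_length,barcode_length Read-1 geometry (nt).
#' @param min_mapq Counting mapping-quality threshold.
#' @param fix_slope,hvg_ratio,n_bins QC options.
#' @param subsample_n,subsample_seed Optional per-cell read subsampling
#'   before counting.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(r1, r2, barcodes, gtf, out_dir,
                            sam_dir = NULL, align_cmd = NULL,
                            spikeins = NULL,
                            umi_length = 6L, barcode_length = 6L,
                            min_mapq = 10L, fix_slope = FALSE,
                            hvg_ratio = 1.5, n_bins = 10L,
                            subsample_n = NULL, subsample_seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("r1", "r2", "barcodes", "gtf")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline_config: input '", f, "' does not exist: ", cfg[[f]])
    }
  }
  if (is.null(align_cmd) && is.null(sam_dir)) {
    stop("pipeline_config: need either align_cmd or sam_dir")
  }
  if (!is.null(spikeins) && !file.exists(spikeins)) {
    stop("pipeline_config: spikeins file does not exist: ", spikeins)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from a flat YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A validated `PipelineConfig`.
#' @export
load_pipeline_config <- function(path) {
  keys <- yaml::read_yaml(path)
  do.call(pipeline_config, keys)
}

# Stable hash of the config for the manifest (content-addressed rerun check).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(cfg))], tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: demultiplex, align (optional), count, QC
#'
#' Executes the stages in order, records per-stage read-conservation
#' tallies, and writes a machine-readable JSON manifest (config hash,
#' stage statuses, output checksums) into the output directory. Re-running
#' with identical inputs and configuration reproduces identical matrices.
#' A stage failure aborts with the failing stage named; the manifest marks
#' the run invalid.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; outputs live under
#'   `config$out_dir` (`demux/`, `counts/`, `qc/`, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- list(package_version = as.character(utils::packageVersion("celseq2")),
                   config_hash = config_hash(unclass(config)),
                   stages = list(), valid = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(err), call. = FALSE)
  }

  # demultiplex
  demux_dir <- file.path(config$out_dir, "demux")
  structure_ <- read_structure(config$umi_length, config$barcode_length)
  barcodes <- read_barcodes(config$barcodes)
  report <- tryCatch(
    demultiplex_run(config$r1, config$r2, barcodes, structure_, demux_dir),
    error = function(e) fail("demux", e))
  write_demux_report(report, file.path(demux_dir, "demux_report.tsv"))
  manifest$stages$demux <- list(
    status = "ok", total = report$total,
    assigned = sum(report$per_barcode), unassigned = report$unassigned,
    too_short = report$too_short)

  # optional per-cell subsampling
  fastqs <- report$files[report$per_barcode > 0]
  if (!is.null(config$subsample_n)) {
    sub_dir <- file.path(config$out_dir, "subsampled")
    dir.create(sub_dir, showWarnings = FALSE)
    fastqs <- vapply(names(fastqs), function(bc) {
      out <- file.path(sub_dir, paste0(bc, ".fastq"))
      subsample_reads(fastqs[[bc]], config$subsample_n,
                      config$subsample_seed, out)
      out
    }, "")
    manifest$stages$subsample <- list(status = "ok", n = config$subsample_n)
  }

  # alignment: external command template, or pre-made SAMs
  if (!is.null(config$align_cmd)) {
    aln_dir <- file.path(config$out_dir, "aligned")
    dir.create(aln_dir, showWarnings = FALSE)
    sams <- vapply(names(fastqs), function(bc) {
      sam <- file.path(aln_dir, paste0(bc, ".sam"))
      cmd <- gsub("{fastq}", fastqs[[bc]],
                  gsub("{sam}", sam, config$align_cmd, fixed = TRUE),
                  fixed = TRUE)
      status <- system(cmd)
      if (status != 0L) {
        fail("align", simpleError(paste0("aligner exit status ", status,
                                         " for ", bc)))
      }
      sam
    }, "")
    manifest$stages$align <- list(status = "ok", n_cells = length(sams))
  } else {
    sams <- list.files(config$sam_dir, pattern = "\\.(sam|bam)$",
                       full.names = TRUE)
    if (length(sams) == 0L) {
      fail("align", simpleError(paste0("no SAM/BAM files in ",
                                       config$sam_dir)))
    }
    manifest$stages$align <- list(status = "skipped_external",
                                  n_cells = length(sams))
  }

  # count
  counts_dir <- file.path(config$out_dir, "counts")
  se <- tryCatch({
    model <- feature_model(config$gtf)
    count_run(sams, model, umi_length = config$umi_length,
              min_mapq = config$min_mapq, cells = names(barcodes))
  }, error = function(e) fail("count", e))
  count_paths <- write_count_matrix(se, counts_dir, mtx = TRUE)
  crep <- S4Vectors::metadata(se)$report
  manifest$stages$count <- c(list(status = "ok"), as.list(crep))

  # qc
  qc_dir <- file.path(config$out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  noise <- gene_noise(se)
  if (nrow(noise) >= 10L && length(unique(noise$mean)) >= 2L) {
    noise <- select_high_variability(noise, ratio = config$hvg_ratio)
  }
  utils::write.table(noise, file.path(qc_dir, "gene_noise.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  det <- detection_curve(se, n_bins = config$n_bins)
  utils::write.table(det, file.path(qc_dir, "detection_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qc_status <- list(status = "ok", n_genes_noise = nrow(noise))
  if (!is.null(config$spikeins)) {
    expected <- read_spikein_expected(config$spikeins)
    tab <- spikein_table(se, expected)
    fit <- tryCatch(estimate_efficiency(tab, fix_slope = config$fix_slope),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      utils::write.table(
        data.frame(slope = fit$slope, intercept_log10 = fit$intercept_log10,
                   efficiency = fit$efficiency, n_points = fit$n_points,
                   n_excluded_zero = fit$n_excluded_zero),
        file.path(qc_dir, "efficiency.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      qc_status$efficiency <- fit$efficiency
      qc_status$slope <- fit$slope
    }
  }
  manifest$stages$qc <- qc_status

  # end-to-end read conservation: demux-assigned reads all reach the counter
  manifest$conservation <- list(
    demux_total = report$total,
    demux_assigned = sum(report$per_barcode),
    count_total = unname(crep[["total"]]))

  outputs <- unlist(count_paths)
  manifest$checksums <- as.list(tools::md5sum(outputs))
  manifest$valid <- TRUE
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
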