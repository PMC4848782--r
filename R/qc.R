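#' Expected spike-in molecules per cell from a concentration sheet
#'
#' Converts an ERCC-style concentration (attomoles per microlitre) into the
#' number of molecules delivered to each cell at a given dilution and spike
#' volume: `attomoles_per_ul * 1e-18 * N_A * volume_ul / dilution_factor`.
#'
#' @param attomoles_per_ul Concentration of the species in the stock mix.
#' @param dilution_factor Fold dilution of the mix before spiking.
#' @param volume_ul Volume spiked per cell, in microlitres.
#' @return Expected molecules per cell.
#' @export
expected_molecules <- function(attomoles_per_ul, dilution_factor, volume_ul) {
  if (any(attomoles_per_ul <= 0) || any(dilution_factor <= 0) ||
      any(volume_ul <= 0)) {
    stop("expected_molecules: all arguments must be positive")
  }
  avogadro <- 6.02214076e23
  attomoles_per_ul * 1e-18 * avogadro * volume_ul / dilution_factor
}

#' Estimate capture efficiency from spike-ins by log-log fit
#'
#' Fits ordinary least squares of `log10(observed mean molecules)` on
#' `log10(expected molecules)` over spike-in species with at least one
#' observed molecule; the y-intercept of this log-log line measures the
#' fraction of input molecules recovered, so efficiency is
#' `10^intercept`. Species never observed cannot enter a log fit and are
#' excluded (their count is reported); no pseudocounts are added since they
#' would bias the intercept, the quantity of interest.
#'
#' @param table data.frame with columns `expected_molecules` (> 0) and
#'   `observed_mean_molecules` (mean molecule estimate across cells); a
#'   `spikein_id` column is carried through if present.
#' @param fix_slope If `TRUE`, constrain the slope to 1 and fit only the
#'   offset; default `FALSE` fits a free slope and reports it.
#' @return An `EfficiencyFit` list: `slope`, `intercept_log10`,
#'   `efficiency` (= 10^intercept), `n_points`, `n_excluded_zero`.
#' @export
estimate_efficiency <- function(table, fix_slope = FALSE) {
  stopifnot(all(c("expected_molecules", "observed_mean_molecules") %in%
                  names(table)))
  if (any(table$expected_molecules <= 0)) {
    stop("estimate_efficiency: expected_molecules must be > 0")
  }
  use <- table$observed_mean_molecules > 0
  n_excluded <- sum(!use)
  if (sum(use) < 3L) {
    stop("estimate_efficiency: need >= 3 spike-ins with observed molecules (",
         sum(use), " available)")
  }
  lx <- log10(table$expected_molecules[use])
  ly <- log10(table$observed_mean_molecules[use])
  if (fix_slope) {
    slope <- 1
    intercept <- mean(ly - lx)
  } else {
    fit <- stats::lm(ly ~ lx)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(list(slope = slope, intercept_log10 = intercept,
                 efficiency = 10^intercept, n_points = sum(use),
                 n_excluded_zero = n_excluded, fix_slope = fix_slope),
            class = "EfficiencyFit")
}

#' @export
print.EfficiencyFit <- function(x, ...) {
  cat(sprintf(
    "EfficiencyFit: efficiency %.3f (10^%.3f), slope %.3f%s, %d spike-ins used (%d with zero observations excluded)\n",
    x$efficiency, x$intercept_log10, x$slope,
    if (x$fix_slope) " [fixed]" else "", x$n_points, x$n_excluded_zero))
  invisible(x)
}

# Accept a SummarizedExperiment (choosing a layer) or a plain matrix.
resolve_layer <- function(x, layer = c("molecule_estimates", "umi_counts")) {
  layer <- match.arg(layer)
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, layer)
  } else {
    as.matrix(x)
  }
}

#' Build a spike-in table from a count matrix and an expected-molecule sheet
#'
#' Averages the observed molecule estimates across all cells for each
#' spike-in species (set `detected_only = TRUE` to average only over cells
#' detecting the species).
#'
#' @param x Count `SummarizedExperiment` or matrix (rows must include the
#'   spike-in ids).
#' @param expected data.frame with columns `spikein_id`,
#'   `expected_molecules`.
#' @param layer Which layer of a `SummarizedExperiment` to use.
#' @param detected_only Average over detecting cells only (default FALSE).
#' @return data.frame with `spikein_id`, `expected_molecules`,
#'   `observed_mean_molecules`.
#' @export
spikein_table <- function(x, expected, layer = "molecule_estimates",
                          detected_only = FALSE) {
  mat <- resolve_layer(x, layer)
  ids <- intersect(expected$spikein_id, rownames(mat))
  sub <- mat[ids, , drop = FALSE]
  obs <- if (detected_only) {
    apply(sub, 1L, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  } else {
    rowMeans(sub)
  }
  data.frame(
    spikein_id = ids,
    expected_molecules =
      expected$expected_molecules[match(ids, expected$spikein_id)],
    observed_mean_molecules = unname(obs), stringsAsFactors = FALSE)
}

#' Per-gene expression noise as the squared coefficient of variation
#'
#' For every gene with nonzero mean across cells, CV^2 = s^2 / mean^2 with
#' the unbiased (n-1) sample variance — material at the 20-72 cell scale
#' these experiments run at. Under pure Poisson sampling CV^2 = 1/mean,
#' which is the baseline the high-variability selection fits.
#'
#' @param x Count `SummarizedExperiment` or genes-by-cells matrix.
#' @param layer Layer to use for a `SummarizedExperiment`.
#' @return data.frame with `gene`, `mean`, `cv2` (genes with mean 0
#'   omitted).
#' @export
gene_noise <- function(x, layer = "molecule_estimates") {
  mat <- resolve_layer(x, layer)
  if (ncol(mat) < 2L) {
    stop("gene_noise: need at least 2 cells to estimate variance")
  }
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, stats::var)
  keep <- mu > 0
  data.frame(gene = rownames(mat)[keep], mean = mu[keep],
             cv2 = v[keep] / mu[keep]^2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag genes with high variability relative to their expression level
#'
#' Fits the noise baseline CV^2 = a/mean + b by least squares (a linear
#' model in 1/mean, the Poisson-plus-offset form these data follow) and
#' flags genes whose CV^2 exceeds `ratio` times their fitted baseline.
#'
#' @param table Output of [gene_noise()].
#' @param ratio Flagging threshold relative to the fitted baseline
#'   (default 1.5).
#' @return The table with added columns `baseline_cv2` and
#'   `high_variability`.
#' @export
select_high_variability <- function(table, ratio = 1.5) {
  if (nrow(table) < 10L) {
    stop("select_high_variability: need >= 10 genes")
  }
  if (length(unique(table$mean)) < 2L) {
    stop("select_high_variability: degenerate fit, all gene means equal")
  }
  inv_mean <- 1 / table$mean
  fit <- stats::lm(table$cv2 ~ inv_mean)
  baseline <- stats::fitted(fit)
  table$baseline_cv2 <- as.numeric(baseline)
  table$high_variability <- table$cv2 > ratio * table$baseline_cv2
  table
}

#' Detection fraction as a function of expression level
#'
#' For each gene, computes its mean expression across cells and the
#' fraction of cells in which it is detected (count > 0); genes are then
#' binned by log-spaced mean-expression bins and the per-bin average
#' detection fraction is reported.
#'
#' @param x Count `SummarizedExperiment` or genes-by-cells matrix.
#' @param n_bins Number of log-spaced expression bins (default 10).
#' @param layer Layer to use for a `SummarizedExperiment`.
#' @return data.frame with `bin`, `mean_expression` (bin geometric center),
#'   `n_genes`, `fraction_detected` (in [0, 1]).
#' @export
detection_curve <- function(x, n_bins = 10L, layer = "molecule_estimates") {
  stopifnot(n_bins >= 1L)
  mat <- resolve_layer(x, layer)
  mu <- rowMeans(mat)
  keep <- mu > 0
  mu <- mu[keep]
  frac <- rowMeans(mat[keep, , drop = FALSE] > 0)
  if (length(mu) == 0L) {
    return(data.frame(bin = integer(0), mean_expression = numeric(0),
                      n_genes = integer(0), fraction_detected = numeric(0)))
  }
  lo <- log10(min(mu))
  hi <- log10(max(mu))
  if (lo == hi) {
    breaks <- c(lo - 0.5, hi + 0.5)
    n_bins <- 1L
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  }
  bin <- cut(log10(mu), breaks, include.lowest = TRUE, labels = FALSE)
  agg <- tapply(frac, bin, mean)
  centers <- 10^((breaks[-length(breaks)] + breaks[-1]) / 2)
  idx <- as.integer(names(agg))
  data.frame(bin = idx, mean_expression = centers[idx],
             n_genes = as.integer(table(bin)[as.character(idx)]),
             fraction_detected = as.numeric(agg), row.names = NULL)
}

#' Read an expected-molecule spike-in sheet
#' @param path TSV with columns `spikein_id`, `expected_molecules`
#'   (header optional).
#' @return data.frame with those two columns.
#' @export
read_spikein_expected <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("spikein_id", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("spikein_id", "expected_molecules")
  tab
}
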