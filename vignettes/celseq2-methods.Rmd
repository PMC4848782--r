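---
title: "Models and methods behind the celseq2 pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the celseq2 pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models, the parameter choices and
the deliberate design decisions in the package, in the order data flows
through the pipeline.

## Cell-barcode design

Cell barcodes are short synthesized oligos; a sequencing error in one must
never make a read look like it came from a different cell. A set whose
minimum pairwise Hamming distance is 2 *detects* every single substitution
(the corrupted sequence is at distance 1 from its origin, hence at distance
≥ 1 from every other member), but cannot uniquely *correct* it — that would
need distance ≥ 3. `design_barcodes` therefore pairs with exact-match
demultiplexing: corrupted barcodes fall into the unassigned pile rather
than the wrong cell.

The construction is greedy accretion over the lexicographic (A<C<G<T)
enumeration of all k-mers: a candidate is accepted iff it satisfies the
composition constraints (GC within bounds, last base not in the forbidden
set) and sits at distance ≥ `min_distance` from every accepted barcode.
The choice is deliberate:

* it is deterministic and order-stable, so two runs with the same
  parameters give byte-identical sets (tested);
* for the default parameters (length 6, distance 2, GC 33–67 %, last base
  ≠ T) it returns far more than the 168 barcodes a 168-well layout needs;
* at lengths ≤ 4 it matches an independently written brute-force greedy
  oracle exactly (tested), so the vectorized implementation is checked
  against first principles.

GC bounds are inclusive: for length 6, 33 % ≤ GC ≤ 67 % admits GC counts
{2, 3, 4} — 2/6 = 33.3 % must be admissible, otherwise no balanced 6-mer
set of practical size exists. Ambiguity codes (N and friends) are rejected
everywhere: barcodes are physical oligos. Maximum-size code construction
is a non-goal; greedy sets are large enough and reproducible.

## Demultiplexing

Read 1 is laid out as UMI (6 nt) then barcode (6 nt) in a 15-base read;
bases 13–15 are ignored. Both lengths are configurable
(`read_structure`), since earlier protocol versions used a 5-nt UMI.

Decisions that needed making:

* **Exact barcode matching only.** A `max-mismatch` style option is a
  natural extension, but with a distance-2 code single-error correction is
  ambiguous by construction, and the design goal is zero misassignment.
  The property is tested literally: injecting one substitution into every
  read's barcode yields zero misassigned reads.
* **UMI travels in the read id.** The UMI is appended to the R2
  identifier as `:UMI:<seq>:CELL:<id>` before the first whitespace.
  Aligners carry the first whitespace-delimited token into the SAM query
  name, so no sidecar file is needed and the counter can reconstruct
  (cell, UMI) for every alignment. The counter treats a missing suffix as
  a hard contract violation rather than guessing.
* **N handling.** N in the barcode can never match a member, so such
  reads are unassigned. N in the UMI is kept through demultiplexing but
  dropped (and counted) by the counter: an N-UMI cannot be compared for
  collisions, yet discarding at demultiplex time would hide the loss from
  the counting report.
* **No quality filtering or trimming.** Qualities pass through
  unmodified; index-read handling belongs to the sequencer's own
  demultiplexer.

`subsample_reads` implements the depth-equalization control (e.g.
300,000 reads per sample): uniform draw without replacement, input order
preserved, byte-identical under a fixed seed.

## Feature assignment and UMI counting

Reads are assigned to genes with **union semantics, strand-specific**: a
read counts for a gene iff the set of genes whose exons overlap any
aligned base on the read's strand has size exactly one. Zero genes →
`no_feature`; two or more → `ambiguous`, and the read is discarded —
accuracy over yield, never a heuristic tie-break. Secondary and
supplementary records are discarded, as are records below mapping quality
10 (multi-mappers); both the flag filter and the threshold are exposed
because alignment pipelines differ in how they mark repeats.

UMIs are collapsed by **exact sequence** within each (cell, gene): reads
sharing a UMI derive from one captured molecule. No within-distance-1
UMI merging is attempted; with 4096 labels and per-gene molecule counts
in the tens to hundreds, sequencing errors in the UMI inflate counts far
less than aggressive merging deflates them, and the collision correction
below assumes exact labels.

### Collision correction

With *m* molecules labelled uniformly at random from *K* = 4^6 = 4096
UMIs, the expected number of distinct labels is
*E[k] = K(1 − (1 − 1/K)^m)*. Inverting at the observed *k* gives

$$\hat m = \frac{\ln(1 - k/K)}{\ln(1 - 1/K)},$$

the binomial occupancy estimate. Properties the tests pin down: 0 ↦ 0 and
1 ↦ 1 exactly; strictly increasing and convex in *k*; never below *k*;
tends to *k* as *K* → ∞; and across 1000 simulated draws at
*m* ∈ {10, 500, 2000} the corrected mean recovers *m* within two standard
errors while the raw distinct count at *m* = 2000 undershoots by more
than 15 %. At saturation (*k* = *K*) the formula diverges; the value for
*k* = *K* − 1 is returned and the entry flagged, keeping the matrix
finite and auditable. The count container is a `SummarizedExperiment`
with two assays — integer distinct-UMI counts and real molecule
estimates — because downstream tools in this ecosystem expect that
container, and the two layers must travel together.

## Spike-in efficiency and noise statistics

**Capture efficiency.** Spike-ins enter every cell at known expected
molecule numbers spanning several decades. Plotting observed mean
molecules against expected molecules on log10–log10 axes, proportional
capture with efficiency *e* gives a unit-slope line with intercept
log10(*e*); the efficiency is read off as 10^intercept. Two open choices
were resolved as follows:

* the slope is fitted freely (and reported) rather than constrained to 1,
  matching a literal linear fit; `fix_slope = TRUE` reproduces the
  constrained variant;
* species with zero observed molecules cannot enter a log fit and are
  excluded with a reported count, in preference to pseudocounts, which
  would bias the intercept — the very quantity being estimated;
* observed means average over **all** cells; averaging only over
  detecting cells is available (`detected_only`) but inflates the low
  end of the ladder.

**Noise.** CV² = variance/mean² per gene, with the unbiased (n−1)
variance: at 20–72 cells the denominator choice is material, and it must
be stated for the Poisson check (CV² = 1/mean) to be exact.
High-variability genes are flagged against a fitted baseline
CV² = a/mean + b (least squares in 1/mean) at a configurable ratio
(default 1.5×): the Poisson term decays as 1/mean while multiplicative
biological noise contributes the constant b, so genes far above the
curve vary more than their expression level explains.

**Detection curves.** Per gene, the fraction of cells with a nonzero
count, averaged within log-spaced mean-expression bins. Genes with zero
mean are excluded (no expression level to bin them at). Under Bernoulli
capture the curve must rise monotonically with expression, which the
tests assert at 500 simulated cells.

## What the simulator emulates — and what it does not

`simulate_run` emulates: per-cell true molecule counts (Poisson around a
log-uniform grid of gene means; gamma-Poisson with a configurable
variance-inflation factor for designated noisy genes), Bernoulli capture
at a set efficiency, uniform random UMI assignment (so collisions occur
at the correct rate), one R2 read per captured molecule drawn from a
fixed window at the gene's 3′ end, R1 composed as UMI + barcode +
padding, substitution errors at configurable per-base rates in the UMI
and barcode segments, and a per-cell SAM holding each read's
by-construction alignment. Defaults mirror the protocol's geometry —
6 + 6 nt in a 15-base R1, 36-base R2, 92 spike-in species, capture
efficiency 0.2 (the order measured for this chemistry on spike-ins) —
with a spike ladder spanning 0.1–5000 molecules per cell, an ERCC-like
dynamic range.

Deliberately not modelled: realistic transcript sequence content, GC
bias, amplification (IVT/PCR) bias, indels, quality-score structure, and
a positional 3′-bias profile beyond the fixed terminal window. The
emitted SAM corresponds to error-free demultiplexing and alignment
(query names carry the post-error UMI but the true cell), so
barcode-error behaviour is exercised through the FASTQ route, and a real
aligner can be substituted via the pipeline's `align_cmd` hook.
Consequently, passing tests demonstrate the correctness of the
*computational* contracts — assignment, collapsing, correction,
estimation — not robustness to artefacts the simulator omits (mapping
errors, chimeras, barcode synthesis errors).

## Problem sizes and numerical choices in the test suite

The suite runs at sizes chosen to make the statistics decisive yet quick:
1000 replicate draws for the collision oracle; 20 seeded replicates of 50
cells × 92 spike-in species for efficiency recovery (the estimate must
land in [0.15, 0.25] with slope in [0.9, 1.1] in at least 18 of 20); 500
cells for the Poisson CV² and detection-monotonicity checks; 5 cells ×
100 genes for the exact end-to-end round trip at capture 1.0. Stochastic
assertions use two-standard-error bands around closed-form expectations,
under fixed seeds. Exact expectations (the 2838.784 molecules behind
2048 distinct UMIs in a 4096 space) were frozen from independent
exact-rational arithmetic before implementation.

## Known limitations

* Alignment itself is out of scope; the counter consumes SAM/BAM.
* Distance-2 codes detect but cannot correct barcode errors; reads with
  corrupted barcodes are lost, not recovered.
* Isoform-level quantification is impossible in a strongly 3′-biased
  protocol and is not attempted.
* The collision correction assumes uniform UMI usage; strong synthesis
  or ligation bias toward particular UMIs would make it undercorrect.
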