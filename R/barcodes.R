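#' Hamming distance between two equal-length DNA strings
#'
#' Number of positions at which `a` and `b` carry different characters.
#' A cell-barcode set whose minimum pairwise Hamming distance is 2 detects
#' any single substitution error: the corrupted barcode can never coincide
#' with a different member of the set.
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming_distance("AAAAAA", "AAAAAC")  # 1
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance: sequences have unequal lengths (",
         nchar(a), " vs ", nchar(b), ")")
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' GC content of a DNA sequence, in percent
#'
#' @param s Character scalar over the alphabet A/C/G/T.
#' @return 100 * (G + C) / length.
#' @examples
#' gc_percent("GCATAT")  # 33.33...
#' @export
gc_percent <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) stop("gc_percent: empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("gc_percent: sequence contains characters outside A/C/G/T: ", s)
  }
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

new_barcode_set <- function(barcodes, length, min_distance, gc_bounds,
                            forbidden_last) {
  structure(
    list(barcodes = barcodes, length = length, min_distance = min_distance,
         gc_bounds = gc_bounds, forbidden_last = forbidden_last),
    class = "BarcodeSet"
  )
}

#' @export
print.BarcodeSet <- function(x, ...) {
  cat(sprintf(
    "BarcodeSet: %d barcodes of length %d nt (min Hamming distance %d, GC %g-%g%%, last base not in {%s})\n",
    length(x$barcodes), x$length, x$min_distance,
    x$gc_bounds[1], x$gc_bounds[2], paste(x$forbidden_last, collapse = ",")))
  invisible(x)
}

#' @export
length.BarcodeSet <- function(x) length(x$barcodes)

# Enumerate all length-k ACGT strings in lexicographic order (A<C<G<T),
# as a character matrix with one row per sequence.
enumerate_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rev(rep(list(bases), k)),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
}

#' Design a cell-barcode set by greedy accretion
#'
#' Enumerates all DNA k-mers in lexicographic order (A<C<G<T), discards those
#' violating the composition constraints (GC percentage outside `gc_bounds`,
#' inclusive, or last base in `forbidden_last`), then greedily accepts a
#' candidate iff its Hamming distance to every already-accepted barcode is at
#' least `min_distance`. The procedure is deterministic, so two calls with
#' identical parameters return identical ordered sets. With the protocol
#' defaults (length 6, distance 2, GC 33-67%, last base not T) the designed
#' set comfortably exceeds the 168 barcodes used on a 96/168-well layout.
#'
#' @param length Barcode length in nt.
#' @param min_distance Minimum pairwise Hamming distance.
#' @param gc_bounds Numeric pair, inclusive GC percentage bounds.
#' @param forbidden_last Character vector of bases the barcode must not end
#'   in (default `"T"`; use `character(0)` for none).
#' @param max_count Optional truncation of the greedy output (e.g. 96 for a
#'   single plate); `NULL` (default) returns the full greedy set.
#' @return A `BarcodeSet` (list with elements `barcodes`, `length`,
#'   `min_distance`, `gc_bounds`, `forbidden_last`).
#' @examples
#' bs <- design_barcodes(4, 2, c(25, 75), "T")
#' length(bs)
#' @export
design_barcodes <- function(length = 6L, min_distance = 2L,
                            gc_bounds = c(33, 67), forbidden_last = "T",
                            max_count = NULL) {
  stopifnot(length >= 1L, min_distance >= 1L,
            all(gc_bounds >= 0), all(gc_bounds <= 100),
            gc_bounds[1] <= gc_bounds[2])
  m <- enumerate_kmers(length)
  gc <- 100 * rowSums(m == "G" | m == "C") / length
  ok <- gc >= gc_bounds[1] & gc <= gc_bounds[2] &
    !(m[, length] %in% forbidden_last)
  if (!any(ok)) {
    warning("design_barcodes: constraints admit no candidate sequences; ",
            "returning an empty set")
    return(new_barcode_set(character(0), as.integer(length),
                           as.integer(min_distance), gc_bounds,
                           forbidden_last))
  }
  m <- m[ok, , drop = FALSE]
  accepted <- matrix(character(0), nrow = 0L, ncol = length)
  for (i in seq_len(nrow(m))) {
    cand <- m[i, ]
    if (nrow(accepted) == 0L ||
        all(rowSums(accepted != matrix(cand, nrow(accepted), length,
                                       byrow = TRUE)) >= min_distance)) {
      accepted <- rbind(accepted, cand)
      if (!is.null(max_count) && nrow(accepted) >= max_count) break
    }
  }
  barcodes <- apply(accepted, 1L, paste0, collapse = "")
  names(barcodes) <- NULL
  new_barcode_set(barcodes, as.integer(length), as.integer(min_distance),
                  gc_bounds, forbidden_last)
}

#' Validate a candidate barcode list against the design constraints
#'
#' Checks every candidate for mixed lengths, non-ACGT characters, GC bounds
#' and forbidden last base, and every unordered pair for Hamming distance
#' below `min_distance`. Nothing raises: all problems are reported.
#'
#' @param candidates Character vector of candidate barcodes.
#' @inheritParams design_barcodes
#' @return A list with `valid` (logical), `violations` (data.frame with
#'   columns `barcode`, `constraint`, `detail`) and `bad_pairs` (data.frame
#'   with `barcode1`, `barcode2`, `distance`).
#' @export
validate_barcode_set <- function(candidates, min_distance = 2L,
                                 gc_bounds = c(0, 100),
                                 forbidden_last = character(0)) {
  viol <- list()
  add <- function(bc, constraint, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      barcode = bc, constraint = constraint, detail = detail,
      stringsAsFactors = FALSE)
  }
  candidates <- as.character(candidates)
  if (anyDuplicated(candidates)) {
    for (d in unique(candidates[duplicated(candidates)]))
      add(d, "duplicate", "sequence occurs more than once")
  }
  lens <- nchar(candidates)
  ref_len <- if (length(candidates)) as.integer(stats::median(lens)) else 0L
  for (i in seq_along(candidates)) {
    bc <- candidates[i]
    if (nchar(bc) != ref_len) {
      add(bc, "length", sprintf("length %d differs from %d", nchar(bc), ref_len))
      next
    }
    chars <- strsplit(bc, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% c("A", "C", "G", "T"))) {
      add(bc, "alphabet", "contains characters outside A/C/G/T")
      next
    }
    gc <- 100 * sum(chars %in% c("G", "C")) / length(chars)
    if (gc < gc_bounds[1] || gc > gc_bounds[2]) {
      add(bc, "gc", sprintf("GC %.1f%% outside [%g, %g]", gc,
                            gc_bounds[1], gc_bounds[2]))
    }
    if (chars[length(chars)] %in% forbidden_last) {
      add(bc, "last_base", sprintf("ends in forbidden base %s",
                                   chars[length(chars)]))
    }
  }
  bad_pairs <- data.frame(barcode1 = character(0), barcode2 = character(0),
                          distance = integer(0), stringsAsFactors = FALSE)
  same_len <- candidates[nchar(candidates) == ref_len]
  if (length(same_len) >= 2L) {
    cm <- do.call(rbind, strsplit(same_len, "", fixed = TRUE))
    for (i in seq_len(length(same_len) - 1L)) {
      d <- rowSums(cm[(i + 1L):length(same_len), , drop = FALSE] !=
                     matrix(cm[i, ], length(same_len) - i, ref_len, byrow = TRUE))
      low <- which(d < min_distance)
      for (j in low) {
        bad_pairs <- rbind(bad_pairs, data.frame(
          barcode1 = same_len[i], barcode2 = same_len[i + j],
          distance = as.integer(d[j]), stringsAsFactors = FALSE))
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(barcode = character(0), constraint = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0L && nrow(bad_pairs) == 0L,
       violations = violations, bad_pairs = bad_pairs)
}

#' Write a barcode set as TSV (barcode_id <TAB> sequence)
#'
#' @param barcode_set A `BarcodeSet` or plain character vector.
#' @param path Output path.
#' @param prefix Id prefix; barcodes are numbered `prefix1`, `prefix2`, ...
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcode_set, path, prefix = "BC") {
  seqs <- if (inherits(barcode_set, "BarcodeSet")) barcode_set$barcodes
          else as.character(barcode_set)
  ids <- paste0(prefix, seq_along(seqs))
  utils::write.table(data.frame(barcode_id = ids, sequence = seqs),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a barcode TSV written by [write_barcodes()]
#'
#' @param path TSV with columns barcode_id, sequence (no header).
#' @return Named character vector: names are barcode ids, values sequences.
#' @export
read_barcodes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("barcode_id", "sequence"))
  stats::setNames(toupper(tab$sequence), tab$barcode_id)
}

# Coerce BarcodeSet / named vector / plain vector to a named sequence vector.
barcode_lookup <- function(barcode_set, prefix = "BC") {
  if (inherits(barcode_set, "BarcodeSet")) {
    stats::setNames(barcode_set$barcodes,
                    paste0(prefix, seq_along(barcode_set$barcodes)))
  } else if (!is.null(names(barcode_set))) {
    barcode_set
  } else {
    stats::setNames(as.character(barcode_set),
                    paste0(prefix, seq_along(barcode_set)))
  }
}
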