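# Amplicon quantification: assign reads to samples by their 6-bp index and
# count hairpins by the 21-mer at the fixed offset (bases 7-27).

HAIRPIN_OFFSET <- 7L
HAIRPIN_LEN <- 21L

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all sequences within `max_mismatch` substitutions of `seq`
mismatch_variants <- function(seq, max_mismatch) {
  out <- seq
  if (max_mismatch >= 1) {
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(seq, "")[[1]]
    for (pos in seq_along(chars)) {
      for (b in setdiff(bases, chars[pos])) {
        v <- chars
        v[pos] <- b
        out <- c(out, paste(v, collapse = ""))
      }
    }
  }
  out
}

# hash from sequence variant -> single owner id, or NA when ambiguous
variant_lookup <- function(seqs, ids, max_mismatch) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  ambiguous <- FALSE
  for (i in seq_along(seqs)) {
    for (v in mismatch_variants(seqs[i], max_mismatch)) {
      prev <- env[[v]]
      if (is.null(prev)) {
        env[[v]] <- ids[i]
      } else if (!identical(prev, ids[i])) {
        env[[v]] <- NA_character_
        ambiguous <- TRUE
      }
    }
  }
  attr(env, "ambiguous") <- ambiguous
  env
}

#' Demultiplex reads by their 6-bp sample index
#'
#' Reads are assigned to the unique sample whose index matches the first
#' six bases; non-matching reads go to the unassigned stream.  Assigned
#' plus unassigned always equals the input.
#'
#' @param reads named character vector of read sequences (as returned by
#'   [simulate_amplicon_reads()] with `path = NULL`) or a FASTQ path.
#' @param sheet a [sample_sheet()]; duplicate indices are an error.
#' @param max_mismatch index mismatches tolerated (0 = exact, the default;
#'   6-bp indices give little room for correction).
#' @return list with `assigned` (named list of per-sample read vectors),
#'   `unassigned` (read vector) and `tally` (per-sample read counts).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 0) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  stopifnot(max_mismatch %in% c(0, 1))
  lut <- variant_lookup(sheet$index, sheet$sample_id, max_mismatch)
  if (isTRUE(attr(lut, "ambiguous"))) {
    stop("sample indices are not separable at max_mismatch = ", max_mismatch)
  }
  idx <- substr(reads, 1L, 6L)
  if (max_mismatch == 0) {
    owner <- sheet$sample_id[match(idx, sheet$index)]
  } else {
    owner <- vapply(idx, function(v) {
      hit <- lut[[v]]
      if (is.null(hit)) NA_character_ else hit
    }, character(1), USE.NAMES = FALSE)
  }
  assigned <- lapply(setNames(sheet$sample_id, sheet$sample_id), function(s) {
    reads[!is.na(owner) & owner == s]
  })
  unassigned <- reads[is.na(owner)]
  tally <- vapply(assigned, length, integer(1))
  list(assigned = assigned, unassigned = unassigned, tally = tally)
}

#' Count hairpins in one sample's reads
#'
#' A read increments hairpin `h` iff the 21-nt window at the fixed offset
#' (bases 7-27) is within `max_mismatch` substitutions of `h`'s target
#' sequence and `h` is the unique such hairpin.  Reads matching no hairpin
#' or more than one are discarded and tallied.
#'
#' @param reads character vector of one sample's reads.
#' @param lib a [hairpin_library()].
#' @param max_mismatch 0 or 1 substitutions in the hairpin window.
#' @param scan if `TRUE`, a read failing at the fixed offset is re-tried at
#'   every offset (fallback for libraries with shifted amplicon structure).
#' @return list with `counts` (named integer vector over all library
#'   hairpins), `n_no_match`, `n_ambiguous`.
#' @export
count_hairpins <- function(reads, lib, max_mismatch = 0, scan = FALSE) {
  stopifnot(max_mismatch %in% c(0, 1))
  lib <- validate_hairpin_library(as.data.frame(lib))
  lut <- variant_lookup(lib$target_sequence, lib$hairpin_id, max_mismatch)
  if (isTRUE(attr(lut, "ambiguous"))) {
    # two hairpins share a variant iff they are within 2*max_mismatch
    warning("library contains hairpins within ", max(1, 2 * max_mismatch),
            " substitutions of each other; their colliding reads are ",
            "discarded as ambiguous")
  }
  counts <- setNames(integer(nrow(lib)), lib$hairpin_id)
  n_no_match <- 0L
  n_ambiguous <- 0L
  window <- substr(reads, HAIRPIN_OFFSET, HAIRPIN_OFFSET + HAIRPIN_LEN - 1L)
  if (max_mismatch == 0 && !scan && !anyDuplicated(lib$target_sequence)) {
    m <- match(window, lib$target_sequence)
    tab <- tabulate(m, nbins = nrow(lib))
    counts <- counts + setNames(as.integer(tab), lib$hairpin_id)
    return(list(counts = counts, n_no_match = sum(is.na(m)),
                n_ambiguous = 0L))
  }
  for (i in seq_along(window)) {
    hit <- lut[[window[i]]]
    if (is.null(hit) && scan) {
      hit <- scan_read(reads[i], lut)
    }
    if (is.null(hit)) {
      n_no_match <- n_no_match + 1L
    } else if (is.na(hit)) {
      n_ambiguous <- n_ambiguous + 1L
    } else {
      counts[hit] <- counts[hit] + 1L
    }
  }
  list(counts = counts, n_no_match = n_no_match, n_ambiguous = n_ambiguous)
}

scan_read <- function(read, lut) {
  L <- nchar(read)
  for (off in seq_len(max(0L, L - HAIRPIN_LEN + 1L))) {
    hit <- lut[[substr(read, off, off + HAIRPIN_LEN - 1L)]]
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Quantify a whole sequencing run into a count matrix
#'
#' Convenience wrapper: demultiplex, count each sample, assemble a
#' [count_matrix()], and report assignment/discard tallies.
#'
#' @inheritParams demultiplex
#' @inheritParams count_hairpins
#' @param index_max_mismatch mismatches tolerated in the 6-bp index.
#' @return list with `counts` (a [count_matrix()]) and `log` (per-sample
#'   assigned / counted / discarded tallies plus the unassigned total).
#' @export
count_screen_fastq <- function(reads, lib, sheet, max_mismatch = 0,
                               index_max_mismatch = 0, scan = FALSE) {
  dm <- demultiplex(reads, sheet, max_mismatch = index_max_mismatch)
  per_sample <- lapply(dm$assigned, count_hairpins, lib = lib,
                       max_mismatch = max_mismatch, scan = scan)
  mat <- vapply(per_sample, `[[`, integer(nrow(lib)), "counts")
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(per_sample),
                                       dimnames = list(lib$hairpin_id,
                                                       names(per_sample)))
  log <- data.frame(
    sample_id = names(per_sample),
    assigned = dm$tally[names(per_sample)],
    counted = vapply(per_sample, function(x) sum(x$counts), numeric(1)),
    no_match = vapply(per_sample, `[[`, integer(1), "n_no_match"),
    ambiguous = vapply(per_sample, `[[`, integer(1), "n_ambiguous"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(log, "unassigned") <- length(dm$unassigned)
  list(counts = count_matrix(mat, sheet), log = log)
}
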