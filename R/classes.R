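#' @importFrom stats median var sd complete.cases dnbinom rnbinom rpois
#'   rlnorm rnorm runif rbinom rbeta pt phyper p.adjust setNames optim
#'   quantile pbeta qt
#' @importFrom utils read.delim write.table head packageVersion
NULL

# ---- hairpin library --------------------------------------------------------

#' Construct a hairpin library annotation table
#'
#' A hairpin library maps each short-hairpin construct to the gene it
#' silences, its 21-nt target (sense) sequence and the sub-pool it was
#' screened in.
#'
#' @param hairpin_id character vector of unique hairpin identifiers.
#' @param gene gene symbol silenced by each hairpin.
#' @param target_sequence 21-nt uppercase DNA target sequence.
#' @param pool pool label (carried for QC; counting is pool-agnostic).
#' @return A `data.frame` of class `hairpin_library`.
#' @export
hairpin_library <- function(hairpin_id, gene, target_sequence,
                            pool = rep("pool1", length(hairpin_id))) {
  lib <- data.frame(
    hairpin_id = as.character(hairpin_id),
    gene = as.character(gene),
    target_sequence = toupper(as.character(target_sequence)),
    pool = as.character(pool),
    stringsAsFactors = FALSE
  )
  validate_hairpin_library(lib)
}

validate_hairpin_library <- function(lib) {
  stopifnot(is.data.frame(lib))
  required <- c("hairpin_id", "gene", "target_sequence", "pool")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    stop("hairpin library is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lib$hairpin_id)) {
    stop("hairpin_id values must be unique")
  }
  bad <- !grepl("^[ACGT]{21}$", lib$target_sequence)
  if (any(bad)) {
    stop("target_sequence must match [ACGT]{21}; offending hairpins: ",
         paste(head(lib$hairpin_id[bad], 5), collapse = ", "))
  }
  class(lib) <- unique(c("hairpin_library", class(lib)))
  lib
}

#' Read / write a hairpin library TSV
#'
#' @param path file path to a tab-separated table with columns
#'   `hairpin_id`, `gene`, `target_sequence`, `pool`.
#' @return `read_hairpin_library()` returns a validated [hairpin_library()].
#' @export
read_hairpin_library <- function(path) {
  lib <- read.delim(path, colClasses = "character")
  validate_hairpin_library(lib)
}

#' @rdname read_hairpin_library
#' @param lib a [hairpin_library()].
#' @export
write_hairpin_library <- function(lib, path) {
  write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- sample sheet -----------------------------------------------------------

#' Construct a screen sample sheet
#'
#' One row per sequenced sample: a 6-bp demultiplexing index, the biological
#' condition (`reference` harvested before treatment, `DMSO` vehicle, or
#' `treated`), the drug arm for treated samples, the harvest day and the
#' biological replicate.
#'
#' @param sample_id unique sample identifiers.
#' @param index 6-bp DNA index per sample.
#' @param condition one of `"reference"`, `"DMSO"`, `"treated"`.
#' @param treatment `"none"` for reference/DMSO, otherwise the drug arm
#'   (e.g. `"PLX"`, `"SCH"`).
#' @param day harvest day, one of 0, 4, 7; reference samples must be day 0.
#' @param replicate biological replicate number.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, index, condition, treatment, day,
                         replicate) {
  sheet <- data.frame(
    sample_id = as.character(sample_id),
    index = toupper(as.character(index)),
    condition = as.character(condition),
    treatment = as.character(treatment),
    day = as.integer(day),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "index", "condition", "treatment", "day",
                "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("sample_id values must be unique")
  if (anyDuplicated(sheet$index)) {
    stop("duplicate 6-bp indices in sample sheet: ",
         paste(unique(sheet$index[duplicated(sheet$index)]), collapse = ", "))
  }
  if (!all(grepl("^[ACGT]{6}$", sheet$index))) {
    stop("every index must be 6 bp of ACGT")
  }
  if (!all(sheet$condition %in% c("reference", "DMSO", "treated"))) {
    stop("condition must be one of reference, DMSO, treated")
  }
  if (!all(sheet$day %in% c(0L, 4L, 7L))) stop("day must be 0, 4 or 7")
  if (any(sheet$condition == "reference" & sheet$day != 0L)) {
    stop("reference samples must be day 0")
  }
  if (any(sheet$condition != "treated" & sheet$treatment != "none")) {
    stop("treatment must be 'none' for reference/DMSO samples")
  }
  class(sheet) <- unique(c("sample_sheet", class(sheet)))
  sheet
}

#' Read / write a sample sheet TSV
#' @param path file path.
#' @return `read_sample_sheet()` returns a validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, colClasses = "character")
  sheet$day <- as.integer(sheet$day)
  sheet$replicate <- as.integer(sheet$replicate)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- count matrix -----------------------------------------------------------

#' Construct a hairpin-by-sample count matrix
#'
#' Integer read counts with hairpins as rows and samples as columns, with
#' the sample sheet attached so downstream contrasts can be resolved by
#' condition/treatment/day.
#'
#' @param counts integer matrix; rownames are hairpin ids, colnames sample
#'   ids.
#' @param samples a [sample_sheet()] covering exactly the columns.
#' @return A matrix of class `count_matrix` with attribute `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have hairpin rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  samples <- validate_sample_sheet(as.data.frame(samples))
  if (!setequal(colnames(counts), samples$sample_id)) {
    stop("count matrix columns must match the sample sheet exactly")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(counts, samples = samples,
            class = c("count_matrix", class(counts)))
}

#' Sample sheet attached to a count matrix
#' @param cm a [count_matrix()].
#' @export
cm_samples <- function(cm) attr(cm, "samples")

#' Read a hairpin count matrix from TSV
#'
#' The TSV has a `hairpin_id` first column and one integer column per
#' sample.  Cells must be non-negative integers; the offending cell is named
#' on failure.
#'
#' @param path counts TSV path.
#' @param samples a [sample_sheet()] (or path to one).
#' @param lib optional [hairpin_library()]; if given, rows are validated
#'   against it.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, samples, lib = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "hairpin_id") {
    stop("first column of a counts TSV must be 'hairpin_id'")
  }
  ids <- raw$hairpin_id
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at hairpin '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(num) <- ids
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_sheet(samples)
  }
  cm <- count_matrix(num, samples)
  if (!is.null(lib)) {
    unknown <- setdiff(rownames(cm), lib$hairpin_id)
    if (length(unknown)) {
      stop("count matrix contains hairpins absent from the library: ",
           paste(head(unknown, 10), collapse = ", "))
    }
  }
  cm
}

#' @rdname read_counts
#' @param cm a [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(hairpin_id = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
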