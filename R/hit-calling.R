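# Two-timepoint filter cascade, dual-screen intersection, gene-level hit
# calling and proteomic evidence integration.

#' Hairpin selection thresholds
#'
#' Defaults encode the published cascade: day-7 depletion to at most 2/3
#' of the DMSO level (fold change <= 0.66) at raw p < 0.05, exclusion of
#' hairpins enriched at day 4 (fold change must be strictly < 1), and a
#' gene needs at least two selected hairpins in both screens.
#'
#' @param day7_fc_max inclusive upper bound on the day-7 fold change.
#' @param p_max exclusive upper bound on the day-7 raw p-value.
#' @param day4_fc_max exclusive upper bound on the day-4 fold change.
#' @param min_hairpins_per_gene per-screen hairpin support for a gene hit.
#' @export
filter_params <- function(day7_fc_max = 0.66, p_max = 0.05,
                          day4_fc_max = 1.0, min_hairpins_per_gene = 2L) {
  stopifnot(day7_fc_max > 0, day7_fc_max < 1, p_max > 0, p_max < 1,
            min_hairpins_per_gene >= 1)
  structure(list(day7_fc_max = day7_fc_max, p_max = p_max,
                 day4_fc_max = day4_fc_max,
                 min_hairpins_per_gene = as.integer(min_hairpins_per_gene)),
            class = "filter_params")
}

#' Select depleted hairpins for one screen arm
#'
#' A hairpin is selected iff its day-7 fold change is `<= day7_fc_max`, its
#' day-7 raw p-value is `< p_max`, and its day-4 fold change is
#' `< day4_fc_max`.  Hairpins absent from the day-4 table fail the day-4
#' clause (conservative) unless `allow_missing_day4 = TRUE`.
#'
#' @param day7,day4 result tables from [screen_differential()] (need
#'   columns `hairpin_id`, `fold_change`, `p_value`).
#' @param fp a [filter_params()].
#' @param screen label for the arm (e.g. `"PLX"`).
#' @param allow_missing_day4 treat hairpins missing from `day4` as passing
#'   the day-4 clause.
#' @return data.frame of class `hairpin_hit_set` with the selected
#'   hairpins, their day-7 fold changes/p-values and day-4 fold changes.
#' @export
select_depleted_hairpins <- function(day7, day4, fp = filter_params(),
                                     screen = "screen",
                                     allow_missing_day4 = FALSE) {
  stopifnot(inherits(fp, "filter_params"))
  extra7 <- setdiff(day7$hairpin_id, day4$hairpin_id)
  extra4 <- setdiff(day4$hairpin_id, day7$hairpin_id)
  if (length(extra7) || length(extra4)) {
    warning(sprintf(
      "day-7/day-4 hairpin universes differ: %d only in day 7, %d only in day 4",
      length(extra7), length(extra4)))
  }
  fc4 <- day4$fold_change[match(day7$hairpin_id, day4$hairpin_id)]
  pass4 <- !is.na(fc4) & fc4 < fp$day4_fc_max
  if (allow_missing_day4) pass4 <- pass4 | is.na(fc4)
  keep <- day7$fold_change <= fp$day7_fc_max &
    day7$p_value < fp$p_max & pass4
  keep[is.na(keep)] <- FALSE
  out <- data.frame(hairpin_id = day7$hairpin_id[keep],
                    fold_change_day7 = day7$fold_change[keep],
                    p_value_day7 = day7$p_value[keep],
                    fold_change_day4 = fc4[keep],
                    stringsAsFactors = FALSE)
  if ("gene" %in% names(day7)) out$gene <- day7$gene[keep]
  out <- out[order(out$hairpin_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  class(out) <- c("hairpin_hit_set", class(out))
  out
}

#' Intersect the hairpin hit sets of two screens
#'
#' @param hits_a,hits_b [select_depleted_hairpins()] outputs.
#' @return sorted character vector of shared hairpin ids.
#' @export
intersect_screens <- function(hits_a, hits_b) {
  sort(intersect(hits_a$hairpin_id, hits_b$hairpin_id))
}

#' Call gene-level hits from two screens
#'
#' A gene qualifies iff at least `min_hairpins_per_gene` of its hairpins
#' were selected in *both* screens.
#'
#' @param hits_a,hits_b per-screen [select_depleted_hairpins()] outputs.
#' @param lib a [hairpin_library()] covering every selected hairpin.
#' @param fp a [filter_params()].
#' @return data.frame with `gene`, per-screen selected-hairpin lists
#'   (`hairpins_a`, `hairpins_b`, semicolon-joined), per-screen counts and
#'   an `evidence_score` column initialized to 2 (one point per supporting
#'   screen); sorted by descending min count, then gene.
#' @export
call_gene_hits <- function(hits_a, hits_b, lib, fp = filter_params()) {
  all_hp <- unique(c(hits_a$hairpin_id, hits_b$hairpin_id))
  unknown <- setdiff(all_hp, lib$hairpin_id)
  if (length(unknown)) {
    stop("hit hairpins absent from the library: ",
         paste(unknown, collapse = ", "))
  }
  gene_of <- setNames(lib$gene, lib$hairpin_id)
  split_a <- split(hits_a$hairpin_id, gene_of[hits_a$hairpin_id])
  split_b <- split(hits_b$hairpin_id, gene_of[hits_b$hairpin_id])
  genes <- intersect(names(split_a), names(split_b))
  n_a <- vapply(split_a[genes], length, integer(1))
  n_b <- vapply(split_b[genes], length, integer(1))
  ok <- n_a >= fp$min_hairpins_per_gene & n_b >= fp$min_hairpins_per_gene
  genes <- genes[ok]
  out <- data.frame(
    gene = genes,
    hairpins_a = vapply(split_a[genes], function(x)
      paste(sort(x), collapse = ";"), character(1)),
    hairpins_b = vapply(split_b[genes], function(x)
      paste(sort(x), collapse = ";"), character(1)),
    n_hairpins_a = n_a[ok],
    n_hairpins_b = n_b[ok],
    stringsAsFactors = FALSE)
  out$evidence_score <- rep(2, nrow(out))
  out <- out[order(-pmin(out$n_hairpins_a, out$n_hairpins_b), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_hits", class(out))
  out
}

#' Integrate screen hits with proteomic regulation evidence
#'
#' Every gene hit starts at score 2 (>= 2 hairpins in each of the two
#' screens).  Each mapped regulator whose proteomic regulation direction is
#' consistent with increased dependence on the target adds one point: an
#' *inhibitor* of the target that is significantly *down*-regulated, or an
#' *activator* that is significantly *up*-regulated.
#'
#' @param gene_hits a [call_gene_hits()] table.
#' @param regulated data.frame of significantly regulated proteins with
#'   columns `gene` (symbol) and `direction` (`"up"`/`"down"`), e.g. from
#'   [apply_regulation_filters()].
#' @param regulator_map data.frame (or TSV path) with columns `regulator`,
#'   `target`, `sign` (`"activates"`/`"inhibits"`); malformed rows are
#'   skipped with a warning.
#' @return `gene_hits` with updated `evidence_score` and a
#'   `supporting_regulators` column, ranked by score then gene.
#' @export
integrate_evidence <- function(gene_hits, regulated, regulator_map) {
  if (is.character(regulator_map) && length(regulator_map) == 1) {
    regulator_map <- read.delim(regulator_map, colClasses = "character")
  }
  required <- c("regulator", "target", "sign")
  if (!all(required %in% names(regulator_map))) {
    stop("regulator map needs columns: ", paste(required, collapse = ", "))
  }
  bad <- !(regulator_map$sign %in% c("activates", "inhibits")) |
    is.na(regulator_map$regulator) | is.na(regulator_map$target) |
    regulator_map$regulator == "" | regulator_map$target == ""
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed regulator-map rows")
    regulator_map <- regulator_map[!bad, , drop = FALSE]
  }
  dir_of <- setNames(regulated$direction, regulated$gene)
  gene_hits$supporting_regulators <- ""
  for (i in seq_len(nrow(gene_hits))) {
    rows <- regulator_map[regulator_map$target == gene_hits$gene[i], ,
                          drop = FALSE]
    if (!nrow(rows)) next
    d <- dir_of[rows$regulator]
    consistent <- (rows$sign == "inhibits" & !is.na(d) & d == "down") |
      (rows$sign == "activates" & !is.na(d) & d == "up")
    gene_hits$evidence_score[i] <- gene_hits$evidence_score[i] +
      sum(consistent)
    gene_hits$supporting_regulators[i] <-
      paste(sort(rows$regulator[consistent]), collapse = ";")
  }
  gene_hits <- gene_hits[order(-gene_hits$evidence_score, gene_hits$gene), ,
                         drop = FALSE]
  rownames(gene_hits) <- NULL
  gene_hits
}
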