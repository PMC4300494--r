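# Triplex-ratio differential analysis: one-sample t-tests of replicate
# log2 ratios against 0 (1 day/control, 3 days/control), a two-sample
# t-test for 3 days vs 1 day, the fold-change/p filter cascade, and the
# phosphosite localization filter.

#' Load a protein ratio table
#'
#' Two dialects are supported.  `"native"`: columns `protein_id`, `gene`
#' and per-replicate log2 ratio columns `ml_log2_r<r>`, `hl_log2_r<r>`,
#' `hm_log2_r<r>` (M/L = 1 day/control, H/L = 3 days/control, H/M = 3
#' days/1 day).  `"maxquant"`: a proteinGroups-like TSV with linear ratio
#' columns `Ratio M/L <r>` etc., which are log2-transformed on load.  In
#' both dialects reverse-database and contaminant rows (id prefixes
#' `REV__`/`CON__`, or `Reverse`/`Potential contaminant` columns marked
#' `+`) are removed.
#'
#' @param path TSV path.
#' @param dialect `"native"` or `"maxquant"`.
#' @param n_replicates replicate columns expected.
#' @return data.frame with the native column layout; the number of removed
#'   reverse/contaminant rows is attached as attribute `"n_removed"`.
#' @export
load_ratio_table <- function(path, dialect = c("native", "maxquant"),
                             n_replicates = 3) {
  dialect <- match.arg(dialect)
  raw <- read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
  if (dialect == "native") {
    needed <- c("protein_id", "gene",
                sprintf("ml_log2_r%d", seq_len(n_replicates)),
                sprintf("hl_log2_r%d", seq_len(n_replicates)),
                sprintf("hm_log2_r%d", seq_len(n_replicates)))
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop("ratio table is missing columns: ", paste(missing, collapse = ", "))
    }
    tab <- raw[, needed]
  } else {
    id_col <- intersect(c("Majority.protein.IDs", "Protein.IDs"),
                        names(raw))[1]
    gene_col <- intersect(c("Gene.names", "Gene.Names"), names(raw))[1]
    if (is.na(id_col)) stop("ratio table is missing columns: Protein IDs")
    ratio_cols <- function(ch) sprintf("Ratio.%s.%d", ch, seq_len(n_replicates))
    needed <- c(ratio_cols("M.L"), ratio_cols("H.L"), ratio_cols("H.M"))
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop("ratio table is missing columns: ", paste(missing, collapse = ", "))
    }
    tab <- data.frame(protein_id = raw[[id_col]],
                      gene = if (is.na(gene_col)) NA_character_ else
                        raw[[gene_col]],
                      log2(as.matrix(raw[, needed])),
                      stringsAsFactors = FALSE)
    names(tab) <- c("protein_id", "gene",
                    sprintf("ml_log2_r%d", seq_len(n_replicates)),
                    sprintf("hl_log2_r%d", seq_len(n_replicates)),
                    sprintf("hm_log2_r%d", seq_len(n_replicates)))
  }
  drop <- grepl("^(REV__|CON__)", tab$protein_id)
  for (flag_col in c("Reverse", "Potential.contaminant")) {
    if (flag_col %in% names(raw)) drop <- drop | raw[[flag_col]] == "+"
  }
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Write a native-dialect ratio table
#' @param tab a ratio table in the native layout.
#' @param path output TSV path.
#' @export
write_ratio_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

signed_fold_change <- function(mean_log2) {
  ifelse(mean_log2 >= 0, 2^mean_log2, -(2^(-mean_log2)))
}

#' One-sample t-test of replicate log2 ratios against 0
#'
#' @param values replicate log2 ratios (NAs dropped).
#' @param min_replicates minimum non-missing values; fewer returns an
#'   excluded result (`NA` statistics).
#' @return one-row data.frame: `n`, `mean_log2`, `fold_change`
#'   (sign-preserving `2^|mean|` convention), `p_value`,
#'   `zero_variance` flag, `excluded` flag.  Zero variance with mean 0
#'   gives p = 1; zero variance with nonzero mean gives p = 0 (flagged).
#' @export
one_sample_test <- function(values, min_replicates = 3) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < min_replicates) {
    return(data.frame(n = n, mean_log2 = NA_real_, fold_change = NA_real_,
                      p_value = NA_real_, zero_variance = FALSE,
                      excluded = TRUE))
  }
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    p <- if (m == 0) 1 else 0
    return(data.frame(n = n, mean_log2 = m,
                      fold_change = signed_fold_change(m), p_value = p,
                      zero_variance = TRUE, excluded = FALSE))
  }
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  data.frame(n = n, mean_log2 = m, fold_change = signed_fold_change(m),
             p_value = p, zero_variance = FALSE, excluded = FALSE)
}

#' Two-sample t-test between two sets of replicate log2 ratios
#'
#' Used for the 3 days/control versus 1 day/control comparison.  Pooled
#' (equal-variance) by default; `welch = TRUE` for unequal variances.
#'
#' @param x,y replicate log2 ratios for the two groups (NAs dropped).
#' @param min_replicates minimum per-group non-missing values.
#' @param welch use the Welch statistic.
#' @return one-row data.frame: `n_x`, `n_y`, `mean_log2` (difference
#'   x - y), `fold_change`, `p_value`, `zero_variance`, `excluded`.
#' @export
two_sample_test <- function(x, y, min_replicates = 3, welch = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < min_replicates || length(y) < min_replicates) {
    return(data.frame(n_x = length(x), n_y = length(y),
                      mean_log2 = NA_real_, fold_change = NA_real_,
                      p_value = NA_real_, zero_variance = FALSE,
                      excluded = TRUE))
  }
  d <- mean(x) - mean(y)
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    p <- if (d == 0) 1 else 0
    return(data.frame(n_x = length(x), n_y = length(y), mean_log2 = d,
                      fold_change = signed_fold_change(d), p_value = p,
                      zero_variance = TRUE, excluded = FALSE))
  }
  if (welch) {
    se2 <- vx / length(x) + vy / length(y)
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                     (vy / length(y))^2 / (length(y) - 1))
  } else {
    sp2 <- ((length(x) - 1) * vx + (length(y) - 1) * vy) /
      (length(x) + length(y) - 2)
    tstat <- d / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    df <- length(x) + length(y) - 2
  }
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(n_x = length(x), n_y = length(y), mean_log2 = d,
             fold_change = signed_fold_change(d), p_value = p,
             zero_variance = FALSE, excluded = FALSE)
}

# Row-wise vectorized versions of the scalar tests; identical formulas,
# used by test_ratio_table() so whole-table runs stay fast.
one_sample_test_rows <- function(m, min_replicates) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1, 1))
  excluded <- n < min_replicates
  zero_var <- !excluded & s == 0
  p <- 2 * pt(abs(mu / (s / sqrt(n))), df = n - 1, lower.tail = FALSE)
  p[zero_var] <- ifelse(mu[zero_var] == 0, 1, 0)
  p[excluded] <- NA_real_
  mu[excluded] <- NA_real_
  data.frame(n = n, mean_log2 = mu, fold_change = signed_fold_change(mu),
             p_value = p, zero_variance = zero_var, excluded = excluded)
}

two_sample_test_rows <- function(mx, my, min_replicates, welch = FALSE) {
  nx <- rowSums(!is.na(mx))
  ny <- rowSums(!is.na(my))
  mux <- rowMeans(mx, na.rm = TRUE)
  muy <- rowMeans(my, na.rm = TRUE)
  vx <- rowSums((mx - mux)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((my - muy)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  d <- mux - muy
  excluded <- nx < min_replicates | ny < min_replicates
  zero_var <- !excluded & vx == 0 & vy == 0
  if (welch) {
    se2 <- vx / nx + vy / ny
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- d / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p[zero_var] <- ifelse(d[zero_var] == 0, 1, 0)
  p[excluded] <- NA_real_
  d[excluded] <- NA_real_
  data.frame(n = nx + ny, mean_log2 = d, fold_change = signed_fold_change(d),
             p_value = p, zero_variance = zero_var, excluded = excluded)
}

ratio_cols <- function(tab, prefix) {
  grep(paste0("^", prefix, "_log2_r[0-9]+$"), names(tab), value = TRUE)
}

#' Run the differential tests over a whole ratio table
#'
#' Applies [one_sample_test()] to the M/L (1 day/control) and H/L (3
#' days/control) ratios and [two_sample_test()] to H/L versus M/L (3 days
#' vs 1 day) for every row.
#'
#' @param tab a native-layout ratio (or phosphosite) table.
#' @param contrasts subset of `c("1d_vs_ctrl", "3d_vs_ctrl", "3d_vs_1d")`.
#' @param id_col column holding the entity id (`"protein_id"` or
#'   `"site_id"`).
#' @param min_replicates,welch passed to the tests.
#' @return data.frame with one row per entity and contrast: id, `gene`
#'   where available, `contrast`, `n`, `mean_log2`, `fold_change`,
#'   `p_value`, `bh_adjusted_p` (BH within contrast over tested rows),
#'   `zero_variance`, `excluded`.
#' @export
test_ratio_table <- function(tab,
                             contrasts = c("1d_vs_ctrl", "3d_vs_ctrl",
                                           "3d_vs_1d"),
                             id_col = "protein_id", min_replicates = 3,
                             welch = FALSE) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  ml <- as.matrix(tab[, ratio_cols(tab, "ml"), drop = FALSE])
  hl <- as.matrix(tab[, ratio_cols(tab, "hl"), drop = FALSE])
  out <- list()
  for (ctr in contrasts) {
    res <- if (ctr == "1d_vs_ctrl") {
      one_sample_test_rows(ml, min_replicates)
    } else if (ctr == "3d_vs_ctrl") {
      one_sample_test_rows(hl, min_replicates)
    } else {
      two_sample_test_rows(hl, ml, min_replicates, welch)
    }
    res <- cbind(data.frame(id = tab[[id_col]], stringsAsFactors = FALSE),
                 res)
    names(res)[1] <- id_col
    if ("gene" %in% names(tab)) res$gene <- tab$gene
    res$contrast <- ctr
    res$bh_adjusted_p <- NA_real_
    tested <- !res$excluded
    res$bh_adjusted_p[tested] <- bh_adjust(res$p_value[tested])
    out[[ctr]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the fold-change / p-value regulation filters
#'
#' An entity is significantly regulated in a contrast iff `p < p_max` and
#' its sign-preserving fold change is `>= fc_min` or `<= -fc_min`
#' (equivalently `|mean log2 ratio| >= log2(fc_min)`, inclusive).
#'
#' @param results output of [test_ratio_table()].
#' @param fc_min fold-change cutoff (symmetric).
#' @param p_max raw p-value cutoff.
#' @param id_col entity id column.
#' @return list with `volcano` (input plus `neg_log10_p`, `significant`,
#'   `direction`), `sets` (per-contrast data.frames of significant
#'   entities), `union` (unique significant ids across contrasts) and
#'   `regulated` (unique id/gene/direction rows for evidence integration,
#'   direction taken from the maximal-|effect| significant contrast).
#' @export
apply_regulation_filters <- function(results, fc_min = 1.5, p_max = 0.05,
                                     id_col = "protein_id") {
  lfc_min <- log2(fc_min)
  sig <- !results$excluded & !is.na(results$p_value) &
    results$p_value < p_max & abs(results$mean_log2) >= lfc_min
  results$significant <- sig
  results$direction <- ifelse(results$mean_log2 >= 0, "up", "down")
  results$neg_log10_p <- -log10(results$p_value)
  sets <- lapply(split(results[sig, , drop = FALSE],
                       results$contrast[sig]), function(df) {
    df[order(df$p_value, df[[id_col]]), , drop = FALSE]
  })
  union_ids <- sort(unique(results[[id_col]][sig]))
  sig_rows <- results[sig, , drop = FALSE]
  if (nrow(sig_rows)) {
    sig_rows <- sig_rows[order(-abs(sig_rows$mean_log2)), , drop = FALSE]
    first <- !duplicated(sig_rows[[id_col]])
    regulated <- data.frame(
      id = sig_rows[[id_col]][first],
      gene = if ("gene" %in% names(sig_rows)) sig_rows$gene[first] else
        sig_rows[[id_col]][first],
      direction = sig_rows$direction[first],
      stringsAsFactors = FALSE)
  } else {
    regulated <- data.frame(id = character(0), gene = character(0),
                            direction = character(0))
  }
  list(volcano = results, sets = sets, union = union_ids,
       regulated = regulated)
}

#' Filter phosphosites on localization probability
#'
#' @param sites phosphosite table with a `localization_probability` column.
#' @param min_prob inclusive threshold (default 0.75).
#' @return the retained rows; the retention fraction is attached as
#'   attribute `"retention"`.
#' @export
filter_phosphosites <- function(sites, min_prob = 0.75) {
  p <- sites$localization_probability
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("localization probabilities must lie in [0, 1]")
  }
  keep <- p >= min_prob
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- mean(keep)
  out
}
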