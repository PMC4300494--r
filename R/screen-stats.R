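# Negative-binomial depletion testing for pooled screens: median-of-ratios
# size factors, method-of-moments dispersions with a parametric 1/mu trend
# and conservative max(raw, trend) sharing, and an exact test conditioned
# on the pooled count.

DISPERSION_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over hairpins (restricted
#' to hairpins with nonzero counts in every sample) of the ratio of that
#' sample's count to the hairpin's geometric mean across samples.
#'
#' @param cm a [count_matrix()] or plain integer matrix.
#' @param pseudo_reference if `TRUE`, hairpins with a positive geometric
#'   mean over the samples where they are observed are used instead of
#'   requiring all-sample-nonzero rows (fallback for sparse matrices).
#' @return named numeric vector of positive per-sample scale factors.
#' @export
estimate_size_factors <- function(cm, pseudo_reference = FALSE) {
  k <- unclass(cm)
  if (ncol(k) < 2) stop("size factors need >= 2 samples")
  logk <- log(k)
  loggeomeans <- rowMeans(logk)
  usable <- is.finite(loggeomeans)
  if (!any(usable)) {
    if (!pseudo_reference) {
      stop("no hairpin has nonzero counts in all samples; re-run with ",
           "pseudo_reference = TRUE to use a pseudo-reference over ",
           "observed samples")
    }
    loggeomeans <- apply(logk, 1, function(x) mean(x[is.finite(x)]))
    usable <- is.finite(loggeomeans)
    if (!any(usable)) stop("count matrix is all zero")
  }
  # median on the linear ratio scale (log-scale medians interpolate
  # geometrically for even counts and drift from the definition)
  geo <- exp(loggeomeans)
  sf <- apply(k, 2, function(kc) {
    median((kc / geo)[usable & kc > 0])
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factor estimation failed (zero/non-finite factors)")
  }
  sf
}

#' Method-of-moments dispersion model with a parametric trend
#'
#' Per-hairpin raw dispersions come from pooled within-group moments of
#' normalized counts: `alpha_i = (v_i - z_i) / mu_i^2` with `v_i` the
#' pooled within-group variance, `mu_i` the base mean of normalized counts
#' and `z_i = mu_i * mean(1/s_j)` the shot-noise term.  A parametric trend
#' `alpha(mu) = a0 + a1/mu` is fit by least squares on the raw values and
#' the final dispersion is the conservative
#' `max(raw, trend, floor)` per hairpin.
#'
#' @param cm a [count_matrix()] or integer matrix.
#' @param sf size factors for the used columns (see
#'   [estimate_size_factors()]).
#' @param groups character/factor vector along columns assigning each
#'   sample to a replicate group; `NA` columns are ignored.
#' @param sharing `"max"` (default, conservative) or `"fit-only"` (use the
#'   trend value everywhere).
#' @return list of class `dispersion_model` with elements `raw`, `trend
#'   coefficients`, `fitted`, `final`, `base_mean`.
#' @export
estimate_dispersions <- function(cm, sf, groups, sharing = c("max", "fit-only")) {
  sharing <- match.arg(sharing)
  k <- unclass(cm)
  use <- !is.na(groups)
  k <- k[, use, drop = FALSE]
  groups <- as.character(groups[use])
  sf <- sf[colnames(k)]
  sizes <- table(groups)
  if (!any(sizes >= 2)) {
    stop("dispersion estimation requires replicates in at least one group")
  }
  q <- sweep(k, 2, sf, "/")
  base_mean <- rowMeans(q)

  rep_groups <- names(sizes)[sizes >= 2]
  ss <- matrix(0, nrow(k), 1)[, 1]
  df <- 0
  for (g in rep_groups) {
    cols <- groups == g
    qg <- q[, cols, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
    df <- df + sum(cols) - 1
  }
  v <- ss / df
  # raw alpha = (var - mu) / mu^2 on normalized counts; keeping the
  # shot-noise term at mu (not mu * mean(1/s)) makes p-values exactly
  # invariant to rescaling a sample together with its size factor
  raw_unclamped <- (v - base_mean) / base_mean^2
  raw <- pmax(raw_unclamped, DISPERSION_FLOOR)

  ok <- is.finite(raw_unclamped) & base_mean > 0
  if (sum(ok) >= 3) {
    x <- 1 / base_mean[ok]
    y <- raw_unclamped[ok]
    fit <- stats::lm.fit(cbind(1, x), y)
    coefs <- fit$coefficients
  } else {
    coefs <- c(0, 0)
  }
  names(coefs) <- c("a0", "a1")
  fitted <- pmax(coefs[1] + coefs[2] / base_mean, 0)
  final <- if (sharing == "max") pmax(raw, fitted, DISPERSION_FLOOR) else
    pmax(fitted, DISPERSION_FLOOR)
  structure(list(raw = raw, raw_unclamped = raw_unclamped,
                 trend_coefficients = coefs, fitted = fitted,
                 final = final, base_mean = base_mean),
            class = "dispersion_model")
}

#' Exact conditioned negative-binomial test for one hairpin
#'
#' Conditions on the pooled count `K = K_A + K_B` of the two group sums.
#' Each group sum is modeled NB with mean `q_hat * sum(s_j)` and variance
#' `sum(q_hat s_j + alpha q_hat^2 s_j^2)` under the common-mean null; the
#' two-sided p-value sums the probabilities of all splits `(a, K - a)` no
#' more likely than the observed one, normalized by the total probability
#' of the pooled count.
#'
#' @param counts_a baseline-group counts (e.g. DMSO).
#' @param counts_b comparison-group counts (e.g. treated).
#' @param sf_a,sf_b size factors for the two groups.
#' @param dispersion the hairpin's final dispersion `alpha*`.
#' @return list with `fold_change` (normalized mean of `b` over `a`; `NaN`
#'   sentinel when both groups are all zero), `base_mean_a`, `base_mean_b`,
#'   `p_value`.
#' @export
nbinom_test <- function(counts_a, counts_b, sf_a, sf_b, dispersion) {
  stopifnot(length(counts_a) == length(sf_a),
            length(counts_b) == length(sf_b),
            is.finite(dispersion), dispersion >= 0)
  alpha <- max(dispersion, DISPERSION_FLOOR)
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  mean_a <- mean(counts_a / sf_a)
  mean_b <- mean(counts_b / sf_b)
  if (ka + kb == 0) {
    return(list(fold_change = NaN, base_mean_a = 0, base_mean_b = 0,
                p_value = 1))
  }
  ks <- ka + kb
  q <- ks / (sum(sf_a) + sum(sf_b))
  mu_a <- q * sum(sf_a)
  mu_b <- q * sum(sf_b)
  var_a <- sum(q * sf_a + alpha * q^2 * sf_a^2)
  var_b <- sum(q * sf_b + alpha * q^2 * sf_b^2)
  size_a <- mu_a^2 / max(var_a - mu_a, mu_a * 1e-8)
  size_b <- mu_b^2 / max(var_b - mu_b, mu_b * 1e-8)
  a <- 0:ks
  ps <- dnbinom(a, mu = mu_a, size = size_a) *
    dnbinom(ks - a, mu = mu_b, size = size_b)
  total <- sum(ps)
  p_obs <- ps[ka + 1]
  p <- if (total <= 0) 1 else min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]) / total)
  list(fold_change = mean_b / mean_a, base_mean_a = mean_a,
       base_mean_b = mean_b, p_value = p)
}

#' Select sample ids from a sample sheet
#'
#' @param sheet a [sample_sheet()].
#' @param condition,treatment,day optional filters; `NULL` matches all.
#' @return character vector of sample ids.
#' @export
select_samples <- function(sheet, condition = NULL, treatment = NULL,
                           day = NULL) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(condition)) keep <- keep & sheet$condition %in% condition
  if (!is.null(treatment)) keep <- keep & sheet$treatment %in% treatment
  if (!is.null(day)) keep <- keep & sheet$day %in% day
  sheet$sample_id[keep]
}

#' Per-hairpin differential depletion analysis for one contrast
#'
#' Runs [nbinom_test()] for every hairpin with at least one nonzero count
#' across the contrast, using median-of-ratios size factors (estimated on
#' the full matrix by default) and the pooled dispersion model.  The fold
#' change is numerator (e.g. treated) over denominator (e.g. DMSO), so
#' `fold_change < 1` means depletion under treatment.
#'
#' @param cm a [count_matrix()].
#' @param numerator,denominator lists of filters passed to
#'   [select_samples()] (e.g. `list(treatment = "PLX", day = 7)`), or
#'   character vectors of sample ids.
#' @param sf optional precomputed size factors; default estimates them on
#'   the full matrix.
#' @param sharing dispersion sharing mode, see [estimate_dispersions()].
#' @param lib optional [hairpin_library()] used to annotate genes.
#' @return data.frame with one row per tested hairpin: `hairpin_id`,
#'   optional `gene`, `base_mean_den`, `base_mean_num`, `fold_change`,
#'   `log2_fold_change`, `p_value`, `bh_adjusted_p`; sorted by p-value then
#'   hairpin id.  Dropped all-zero hairpins are recorded in the
#'   `"dropped"` attribute.
#' @export
screen_differential <- function(cm, numerator, denominator, sf = NULL,
                                sharing = "max", lib = NULL) {
  sheet <- cm_samples(cm)
  ids_num <- if (is.list(numerator)) do.call(select_samples,
                                             c(list(sheet), numerator)) else
    numerator
  ids_den <- if (is.list(denominator)) do.call(select_samples,
                                               c(list(sheet), denominator)) else
    denominator
  if (!length(ids_num) || !length(ids_den)) {
    stop("empty contrast group: numerator has ", length(ids_num),
         " samples, denominator has ", length(ids_den))
  }
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  k <- unclass(cm)
  groups <- rep(NA_character_, ncol(k))
  names(groups) <- colnames(k)
  groups[ids_den] <- "den"
  groups[ids_num] <- "num"
  disp <- estimate_dispersions(cm, sf, groups, sharing = sharing)

  sub <- k[, c(ids_den, ids_num), drop = FALSE]
  tested <- rowSums(sub) > 0
  dropped <- rownames(k)[!tested]
  res <- lapply(which(tested), function(i) {
    nbinom_test(k[i, ids_den], k[i, ids_num], sf[ids_den], sf[ids_num],
                disp$final[i])
  })
  out <- data.frame(
    hairpin_id = rownames(k)[tested],
    base_mean_den = vapply(res, `[[`, numeric(1), "base_mean_a"),
    base_mean_num = vapply(res, `[[`, numeric(1), "base_mean_b"),
    fold_change = vapply(res, `[[`, numeric(1), "fold_change"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$log2_fold_change <- log2(out$fold_change)
  out$bh_adjusted_p <- bh_adjust(out$p_value)
  if (!is.null(lib)) {
    out$gene <- lib$gene[match(out$hairpin_id, lib$hairpin_id)]
  }
  out <- out[order(out$p_value, out$hairpin_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  cols <- c("hairpin_id", if (!is.null(lib)) "gene", "base_mean_den",
            "base_mean_num", "fold_change", "log2_fold_change", "p_value",
            "bh_adjusted_p")
  out <- out[, cols]
  attr(out, "dropped") <- dropped
  attr(out, "size_factors") <- sf
  out
}
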