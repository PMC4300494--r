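# Plate-reader viability normalization and four-parameter logistic (4PL)
# dose-response fitting with analytic ICx inversion.

#' Normalize raw viability readings to percent
#'
#' Linear map anchored on the plate controls: the untreated negative
#' control defines 100% viability and the kill control (e.g. phenylarsine
#' oxide) defines 0%.
#'
#' @param raw raw readings.
#' @param neg_ctrl_mean mean untreated-control reading (100%).
#' @param pos_ctrl_mean mean kill-control reading (0%).
#' @return percent viability; values outside \[-20, 120\] are flagged via
#'   the `"n_extreme"` attribute (noise can push readings outside
#'   \[0, 100\]).
#' @export
normalize_viability <- function(raw, neg_ctrl_mean, pos_ctrl_mean) {
  if (neg_ctrl_mean == pos_ctrl_mean) {
    stop("negative and positive control means are equal; cannot normalize")
  }
  pct <- 100 * (raw - pos_ctrl_mean) / (neg_ctrl_mean - pos_ctrl_mean)
  attr(pct, "n_extreme") <- sum(pct < -20 | pct > 120)
  pct
}

# 4PL response: viability(c) = bottom + (top - bottom)/(1 + (c/ic50)^hill)
four_pl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)` with a
#' deterministic multi-start grid (hill in \{0.5, 1, 2\}, ic50 at dose
#' quantiles) refined by Nelder-Mead on `(top, bottom, log ic50,
#' log hill)`.  ICx values are solved analytically from the fitted
#' parameters.
#'
#' @param concentrations dose vector (> 0), at least 5 distinct values
#'   spanning >= 2 log10 units.
#' @param percents normalized percent viability, same length.
#' @param icx inhibition percentages to solve for (e.g. `c(20, 50)`).
#' @param min_r2 fits explaining less variance than this are rejected as
#'   degenerate (flat response).
#' @return list of class `dose_response_fit`: `top`, `bottom`, `ic50`,
#'   `hill`, `rss`, `r_squared` and an `icx` named vector (NA where the
#'   asymptotes do not bracket the requested level).
#' @export
fit_dose_response <- function(concentrations, percents, icx = c(20, 50),
                              min_r2 = 0.3) {
  stopifnot(length(concentrations) == length(percents),
            all(concentrations > 0))
  if (length(unique(concentrations)) < 5) {
    stop("need >= 5 distinct concentrations")
  }
  if (diff(range(log10(concentrations))) < 2) {
    stop("concentrations must span >= 2 log10 units")
  }
  obj <- function(par) {
    pred <- four_pl(concentrations, par[1], par[2], exp(par[3]), exp(par[4]))
    sum((percents - pred)^2)
  }
  top0 <- max(percents)
  bottom0 <- min(percents)
  starts <- expand.grid(
    hill = c(0.5, 1, 2),
    ic50 = quantile(concentrations, c(0.25, 0.5, 0.75), names = FALSE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(top0, bottom0, log(starts$ic50[i]), log(starts$hill[i]))
    fit <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    # polish: a second pass from the current optimum
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  top <- par[1]
  bottom <- par[2]
  ic50 <- exp(par[3])
  hill <- exp(par[4])
  if (bottom > top) {  # canonicalize orientation
    tmp <- top
    top <- bottom
    bottom <- tmp
    hill <- -hill
  }
  tss <- sum((percents - mean(percents))^2)
  r2 <- if (tss > 0) 1 - best$value / tss else 0
  if (!is.finite(r2) || r2 < min_r2) {
    stop("degenerate fit: response is too flat to support a dose-response ",
         "model (R^2 = ", signif(max(r2, 0), 3), ")")
  }
  icx_vals <- vapply(icx, function(x) {
    target <- 100 - x  # x% inhibition = (100 - x)% residual viability
    if (target <= bottom || target >= top) return(NA_real_)
    ratio <- (top - bottom) / (target - bottom) - 1
    ic50 * ratio^(1 / hill)
  }, numeric(1))
  names(icx_vals) <- paste0("IC", icx)
  structure(list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
                 rss = best$value, r_squared = r2, icx = icx_vals),
            class = "dose_response_fit")
}
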