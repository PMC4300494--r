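# Synthetic triplex-ratio proteome generator.  Channels: L = control,
# M = 1 day, H = 3 days of drug treatment; replicate log2 ratios are Normal
# around planted per-protein log2 fold changes.

#' Configuration for the synthetic triplex proteome
#'
#' @param n_proteins number of quantified proteins.
#' @param n_replicates biological replicates (triplex runs).
#' @param frac_regulated proportion of proteins given a planted effect.
#' @param effect_log2fc_range interval for the planted |log2 FC| at 3
#'   days/control; the 1 day/control effect is drawn from the same interval
#'   with the same sign.
#' @param noise_sd replicate standard deviation of log2 ratios.
#' @param frac_phospho proportion of proteins that receive phosphosites.
#' @param sites_per_protein maximum phosphosites simulated per
#'   phosphoprotein (uniform in 1..max).
#' @param loc_prob_model mixture for localization probabilities:
#'   `list(frac_high, high = c(shape1, shape2), low = c(shape1, shape2))` —
#'   a well-localized Beta component and a poorly localized one.
#' @param seed RNG seed.
#' @return list of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 3800, n_replicates = 3,
                                frac_regulated = 0.15,
                                effect_log2fc_range = c(log2(1.5), 2),
                                noise_sd = 0.2,
                                frac_phospho = 0.5, sites_per_protein = 3,
                                loc_prob_model = list(
                                  frac_high = 0.8,
                                  high = c(20, 1), low = c(2, 2)),
                                seed = 1L) {
  if (frac_regulated < 0 || frac_regulated > 1) {
    stop("frac_regulated must be in [0, 1]")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(
    n_proteins = n_proteins, n_replicates = n_replicates,
    frac_regulated = frac_regulated,
    effect_log2fc_range = effect_log2fc_range, noise_sd = noise_sd,
    frac_phospho = frac_phospho, sites_per_protein = sites_per_protein,
    loc_prob_model = loc_prob_model, seed = seed
  ), class = "proteome_sim_config")
}

#' True probability mass above a localization threshold
#'
#' Closed-form mass of the configured Beta mixture above `min_prob`; used
#' as the oracle for retention-fraction checks.
#'
#' @param cfg a [proteome_sim_config()].
#' @param min_prob localization threshold.
#' @export
loc_prob_mass_above <- function(cfg, min_prob = 0.75) {
  m <- cfg$loc_prob_model
  m$frac_high * pbeta(min_prob, m$high[1], m$high[2], lower.tail = FALSE) +
    (1 - m$frac_high) * pbeta(min_prob, m$low[1], m$low[2],
                              lower.tail = FALSE)
}

#' Simulate a triplex-ratio proteome with planted regulation
#'
#' Per-protein per-replicate log2 ratios are Normal(true log2 FC, noise_sd)
#' for M/L (1 day/control) and H/L (3 days/control); H/M is simulated with
#' its own independent noise around the difference of the two planted
#' effects, mimicking that the three ratios are measured, not derived.
#'
#' @param cfg a [proteome_sim_config()].
#' @return list with `proteins` (a protein ratio table, see
#'   [load_ratio_table()]), `phospho` (phosphosite table) and `truth`
#'   (planted per-protein log2 effects).
#' @export
simulate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "proteome_sim_config"))
  withr::with_seed(cfg$seed, simulate_proteome_impl(cfg))
}

simulate_proteome_impl <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  genes <- sprintf("GENE%05d", seq_len(n))
  n_reg <- round(cfg$frac_regulated * n)
  regulated <- rep(FALSE, n)
  if (n_reg > 0) regulated[sample.int(n, n_reg)] <- TRUE

  lfc1 <- lfc3 <- numeric(n)
  if (n_reg > 0) {
    sgn <- sample(c(-1, 1), n_reg, replace = TRUE)
    lfc3[regulated] <- sgn * runif(n_reg, cfg$effect_log2fc_range[1],
                                   cfg$effect_log2fc_range[2])
    lfc1[regulated] <- sgn * runif(n_reg, cfg$effect_log2fc_range[1],
                                   cfg$effect_log2fc_range[2])
  }

  r <- cfg$n_replicates
  ml <- matrix(rnorm(n * r, mean = lfc1, sd = cfg$noise_sd), nrow = n)
  hl <- matrix(rnorm(n * r, mean = lfc3, sd = cfg$noise_sd), nrow = n)
  hm <- matrix(rnorm(n * r, mean = lfc3 - lfc1, sd = cfg$noise_sd), nrow = n)
  colnames(ml) <- sprintf("ml_log2_r%d", seq_len(r))
  colnames(hl) <- sprintf("hl_log2_r%d", seq_len(r))
  colnames(hm) <- sprintf("hm_log2_r%d", seq_len(r))

  proteins <- data.frame(protein_id = ids, gene = genes, ml, hl, hm,
                         stringsAsFactors = FALSE)

  n_ph <- round(cfg$frac_phospho * n)
  phospho <- NULL
  if (n_ph > 0) {
    ph_idx <- sort(sample.int(n, n_ph))
    n_sites <- sample.int(cfg$sites_per_protein, n_ph, replace = TRUE)
    prot_row <- rep(ph_idx, times = n_sites)
    total <- length(prot_row)
    m <- cfg$loc_prob_model
    from_high <- runif(total) < m$frac_high
    prob <- ifelse(from_high,
                   rbeta(total, m$high[1], m$high[2]),
                   rbeta(total, m$low[1], m$low[2]))
    ml_s <- matrix(rnorm(total * r, mean = lfc1[prot_row],
                         sd = cfg$noise_sd), nrow = total)
    hl_s <- matrix(rnorm(total * r, mean = lfc3[prot_row],
                         sd = cfg$noise_sd), nrow = total)
    hm_s <- matrix(rnorm(total * r, mean = (lfc3 - lfc1)[prot_row],
                         sd = cfg$noise_sd), nrow = total)
    colnames(ml_s) <- colnames(ml)
    colnames(hl_s) <- colnames(hl)
    colnames(hm_s) <- colnames(hm)
    phospho <- data.frame(
      protein_id = ids[prot_row],
      site_id = sprintf("%s_site%d", ids[prot_row],
                        unlist(lapply(n_sites, seq_len))),
      position = sample.int(1000, total, replace = TRUE),
      residue = sample(c("S", "T", "Y"), total, replace = TRUE,
                       prob = c(0.75, 0.2, 0.05)),
      localization_probability = prob,
      ml_s, hl_s, hm_s, stringsAsFactors = FALSE)
  }

  truth <- data.frame(protein_id = ids, gene = genes,
                      true_log2fc_1d = lfc1, true_log2fc_3d = lfc3,
                      is_planted = regulated, stringsAsFactors = FALSE)
  list(proteins = proteins, phospho = phospho, truth = truth)
}
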