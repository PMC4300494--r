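# Synthetic pooled-screen generator with planted, recoverable ground truth.
# The stated world: a kinome-scale library (~500 genes x ~8 hairpins in 4
# pools), three biological replicates, a reference sample harvested at day 0
# and DMSO/treated samples harvested at days 4 and 7 for each drug arm.

#' Configuration for the synthetic dropout screen
#'
#' @param n_genes number of genes in the library.
#' @param hairpins_per_gene hairpins targeting each gene (>= 1).
#' @param n_pools number of library sub-pools (round-robin assignment).
#' @param depth_mean expected reads per hairpin per sample before abundance
#'   skew and size-factor heterogeneity.
#' @param dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param n_replicates biological replicates.
#' @param planted_sensitizers `data.frame(gene, fc_day7, fc_day4)` of
#'   sensitizer genes: per-hairpin fold change of treated vs DMSO at each
#'   day.  Effects apply in the arms named by `arms`.
#' @param planted_essentials `data.frame(gene, fc)` of genes depleted in all
#'   day > 0 samples relative to the reference (DMSO-vs-reference fold
#'   change).
#' @param arms treated arms sharing every planted sensitizer effect.
#' @param frac_hairpins_affected fraction of each planted gene's hairpins
#'   that actually carry the effect (1 = all; lower values exercise the
#'   >= 2-hairpin rule).
#' @param abundance_sdlog log-normal sd of per-hairpin library
#'   representation skew.
#' @param size_factor_range samples get depth multipliers drawn log-uniform
#'   in this interval.
#' @param seed RNG seed; identical seeds reproduce identical outputs.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 500, hairpins_per_gene = 8,
                              n_pools = 4, depth_mean = 300,
                              dispersion = 0.05, n_replicates = 3,
                              planted_sensitizers = NULL,
                              planted_essentials = NULL,
                              arms = c("PLX", "SCH"),
                              frac_hairpins_affected = 1,
                              abundance_sdlog = 0.5,
                              size_factor_range = c(0.5, 2),
                              seed = 1L) {
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (hairpins_per_gene < 1) stop("hairpins_per_gene must be >= 1")
  if (!is.null(planted_sensitizers)) {
    stopifnot(all(c("gene", "fc_day7", "fc_day4") %in%
                    names(planted_sensitizers)))
    if (any(planted_sensitizers$fc_day7 <= 0) ||
        any(planted_sensitizers$fc_day4 <= 0)) {
      stop("planted fold changes must be > 0")
    }
  }
  if (!is.null(planted_essentials)) {
    stopifnot(all(c("gene", "fc") %in% names(planted_essentials)))
    if (any(planted_essentials$fc <= 0)) stop("planted fold changes must be > 0")
  }
  structure(list(
    n_genes = n_genes, hairpins_per_gene = hairpins_per_gene,
    n_pools = n_pools, depth_mean = depth_mean, dispersion = dispersion,
    n_replicates = n_replicates,
    planted_sensitizers = planted_sensitizers,
    planted_essentials = planted_essentials,
    arms = arms, frac_hairpins_affected = frac_hairpins_affected,
    abundance_sdlog = abundance_sdlog,
    size_factor_range = size_factor_range, seed = seed
  ), class = "screen_sim_config")
}

# 6-bp indices with pairwise Hamming distance >= 3 so one substitution can
# never flip a read between samples even under mismatch-tolerant demux.
generate_indices <- function(n) {
  bases <- c("A", "C", "G", "T")
  chosen <- character(0)
  chosen_mat <- matrix(character(0), nrow = 0, ncol = 6)
  tries <- 0
  while (length(chosen) < n) {
    tries <- tries + 1
    if (tries > 20000) stop("could not generate ", n, " well-separated indices")
    cand <- sample(bases, 6, replace = TRUE)
    if (nrow(chosen_mat) == 0 ||
        all(rowSums(chosen_mat != matrix(cand, nrow(chosen_mat), 6,
                                         byrow = TRUE)) >= 3)) {
      chosen_mat <- rbind(chosen_mat, cand)
      chosen <- c(chosen, paste(cand, collapse = ""))
    }
  }
  chosen
}

random_kmers <- function(n, k) {
  bases <- c("A", "C", "G", "T")
  seqs <- unique(vapply(seq_len(2 * n + 10), function(i) {
    paste(sample(bases, k, replace = TRUE), collapse = "")
  }, character(1)))
  while (length(seqs) < n) {
    seqs <- unique(c(seqs, vapply(seq_len(n), function(i) {
      paste(sample(bases, k, replace = TRUE), collapse = "")
    }, character(1))))
  }
  seqs[seq_len(n)]
}

#' Simulate a pooled shRNA dropout screen
#'
#' Counts are drawn NB(mu, alpha) with
#' `mu = depth_mean * hairpin abundance * condition fold change * sample
#' size factor`.  Planted sensitizer effects act on treated samples
#' (relative to DMSO) at days 4 and 7; planted essentials act on every
#' day > 0 sample relative to the reference.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with elements `library` ([hairpin_library()]), `samples`
#'   ([sample_sheet()]), `counts` ([count_matrix()]) and `truth`
#'   (data.frame of planted per-hairpin effects per arm/day).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  withr::with_seed(cfg$seed, simulate_screen_impl(cfg))
}

simulate_screen_impl <- function(cfg) {
  n_hp <- cfg$n_genes * cfg$hairpins_per_gene
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  hp_gene <- rep(genes, each = cfg$hairpins_per_gene)
  hp_id <- sprintf("hp%05d", seq_len(n_hp))
  lib <- hairpin_library(
    hairpin_id = hp_id, gene = hp_gene,
    target_sequence = random_kmers(n_hp, 21),
    pool = paste0("pool", ((seq_len(n_hp) - 1) %% cfg$n_pools) + 1)
  )

  # sample design: reference day 0 + DMSO/treated at days 4 and 7 per rep
  rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    rows[[length(rows) + 1]] <- data.frame(
      condition = "reference", treatment = "none", day = 0L, replicate = r)
    for (d in c(4L, 7L)) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = "DMSO", treatment = "none", day = d, replicate = r)
      for (arm in cfg$arms) {
        rows[[length(rows) + 1]] <- data.frame(
          condition = "treated", treatment = arm, day = d, replicate = r)
      }
    }
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s_%s_d%d_r%d",
                              ifelse(design$condition == "treated",
                                     design$treatment, design$condition),
                              design$condition, design$day, design$replicate)
  sheet <- sample_sheet(design$sample_id, generate_indices(nrow(design)),
                        design$condition, design$treatment, design$day,
                        design$replicate)

  abundance <- rlnorm(n_hp, meanlog = -cfg$abundance_sdlog^2 / 2,
                      sdlog = cfg$abundance_sdlog)
  sf <- exp(runif(nrow(sheet), log(cfg$size_factor_range[1]),
                  log(cfg$size_factor_range[2])))

  # per-hairpin fold-change map; columns indexed by (arm or condition, day)
  fc <- matrix(1, nrow = n_hp, ncol = nrow(sheet),
               dimnames = list(hp_id, sheet$sample_id))
  truth <- list()
  if (!is.null(cfg$planted_essentials)) {
    for (i in seq_len(nrow(cfg$planted_essentials))) {
      g <- cfg$planted_essentials$gene[i]
      f <- cfg$planted_essentials$fc[i]
      hps <- hp_id[hp_gene == g]
      cols <- sheet$day > 0L
      fc[hps, cols] <- fc[hps, cols] * f
      truth[[length(truth) + 1]] <- data.frame(
        entity = hps, gene = g, contrast = "DMSO_vs_reference",
        arm = "none", true_fc = f, is_planted = TRUE)
    }
  }
  if (!is.null(cfg$planted_sensitizers)) {
    for (i in seq_len(nrow(cfg$planted_sensitizers))) {
      g <- cfg$planted_sensitizers$gene[i]
      hps <- hp_id[hp_gene == g]
      if (cfg$frac_hairpins_affected < 1) {
        k <- max(1, round(cfg$frac_hairpins_affected * length(hps)))
        hps <- sort(sample(hps, k))
      }
      for (arm in cfg$arms) {
        for (d in c(4L, 7L)) {
          f <- if (d == 7L) cfg$planted_sensitizers$fc_day7[i] else
            cfg$planted_sensitizers$fc_day4[i]
          cols <- sheet$condition == "treated" & sheet$treatment == arm &
            sheet$day == d
          fc[hps, cols] <- fc[hps, cols] * f
          truth[[length(truth) + 1]] <- data.frame(
            entity = hps, gene = g,
            contrast = sprintf("treated_vs_DMSO_day%d", d),
            arm = arm, true_fc = f, is_planted = TRUE)
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(entity = character(0), gene = character(0),
               contrast = character(0), arm = character(0),
               true_fc = numeric(0), is_planted = logical(0))

  mu <- (cfg$depth_mean * abundance) %o% sf * fc
  counts <- if (cfg$dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           nrow = n_hp, dimnames = dimnames(fc))
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = n_hp,
           dimnames = dimnames(fc))
  }
  list(library = lib, samples = sheet,
       counts = count_matrix(counts, sheet), truth = truth)
}

# fixed amplicon layout: bases 1-6 sample index, 7-27 hairpin sense 21-mer,
# then a constant 3' region shared by all reads
AMPLICON_CONSTANT <- "GTTTTAGAGCTAGAAATAGC"

#' Simulate indexed amplicon reads from a count matrix
#'
#' Emits one read per count unit with the fixed layout: bases 1-6 sample
#' index, bases 7-27 the hairpin 21-nt target sequence, then a constant
#' region.  Per-base substitution errors are applied at `error_rate`.
#'
#' @param counts a [count_matrix()].
#' @param lib a [hairpin_library()] covering every counted hairpin.
#' @param sheet a [sample_sheet()]; indices must be distinct.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param path output FASTQ path (".gz" suffix gzips); `NULL` returns the
#'   records as a character vector of read sequences with names encoding
#'   read ids.
#' @return Invisibly, the path (or the in-memory reads when `path` is
#'   `NULL`).
#' @export
simulate_amplicon_reads <- function(counts, lib, sheet, error_rate = 0,
                                    seed = 1L, path = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1)
  missing_hp <- setdiff(rownames(counts), lib$hairpin_id)
  if (length(missing_hp)) {
    stop("counts contain hairpins absent from the library: ",
         paste(head(missing_hp, 5), collapse = ", "))
  }
  if (anyDuplicated(sheet$index)) stop("duplicate indices in sample sheet")
  withr::with_seed(seed, {
    seq_of <- setNames(lib$target_sequence, lib$hairpin_id)
    idx_of <- setNames(sheet$index, sheet$sample_id)
    reads <- character(0)
    for (s in colnames(counts)) {
      n_per_hp <- counts[, s]
      n_per_hp <- n_per_hp[n_per_hp > 0]
      if (!length(n_per_hp)) next
      templ <- paste0(idx_of[[s]], seq_of[names(n_per_hp)],
                      AMPLICON_CONSTANT)
      reads <- c(reads, rep(templ, times = n_per_hp))
    }
    if (length(reads) && error_rate > 0) {
      reads <- apply_substitutions(reads, error_rate)
    }
    if (length(reads)) {
      names(reads) <- sprintf("read%07d", seq_along(reads))
    }
    if (is.null(path)) return(invisible(reads))
    write_fastq(reads, path)
    invisible(path)
  })
}

apply_substitutions <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(reads, ""))
  hit <- matrix(runif(length(mat)) < error_rate, nrow = nrow(mat))
  if (any(hit)) {
    # substitute with one of the three other bases, uniformly
    old <- mat[hit]
    shift <- sample(1:3, sum(hit), replace = TRUE)
    mat[hit] <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
  }
  apply(mat, 1, paste, collapse = "")
}

write_fastq <- function(reads, path) {
  if (!length(reads)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    close(con)
    return(invisible(path))
  }
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- names(reads)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), names(dna))
}
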