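# Triplex-ratio differential analysis: table loading, t-tests against
# reference formulas, the filter cascade and phosphosite filtering.

write_native_table <- function(tab) {
  path <- file.path(tempdir(), "ratios.tsv")
  write_ratio_table(tab, path)
  path
}

test_that("ratio table loading removes reverse/contaminant rows", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 20, seed = 3))
  tab <- sim$proteins
  tab$protein_id[1] <- "CON__P00001"
  tab$protein_id[2] <- "REV__P00002"
  path <- write_native_table(tab)
  loaded <- load_ratio_table(path)
  expect_equal(nrow(loaded), 18)
  expect_equal(attr(loaded, "n_removed"), 2)
  expect_false(any(grepl("^(CON|REV)__", loaded$protein_id)))

  # lossless round trip for clean tables
  clean <- sim$proteins
  path2 <- write_native_table(clean)
  back <- load_ratio_table(path2)
  expect_equal(back$ml_log2_r1, clean$ml_log2_r1, tolerance = 1e-12)
  unlink(c(path, path2))
})

test_that("maxquant dialect log2-transforms linear ratios", {
  mq <- data.frame(
    "Majority protein IDs" = c("P1", "P2", "CON__P3"),
    "Gene names" = c("A", "B", "C"),
    check.names = FALSE)
  for (ch in c("M/L", "H/L", "H/M")) {
    for (r in 1:3) mq[[sprintf("Ratio %s %d", ch, r)]] <- c(1.0, 2.0, 1.0)
  }
  path <- file.path(tempdir(), "mq.tsv")
  write.table(mq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- load_ratio_table(path, dialect = "maxquant")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ml_log2_r1, c(0, 1))  # linear 1 -> log2 0, linear 2 -> 1
  unlink(path)
})

test_that("one-sample t-test matches the textbook formula", {
  r0 <- one_sample_test(c(0, 0, 0))
  expect_equal(r0$p_value, 1)
  expect_true(r0$zero_variance)

  r <- one_sample_test(c(1.0, 1.2, 0.8))
  expect_equal(r$mean_log2, 1.0)
  tstat <- 1.0 / (0.2 / sqrt(3))
  expect_equal(tstat, 8.660254, tolerance = 1e-6)
  expect_equal(r$p_value, 2 * pt(tstat, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p_value, oracle_one_sample_p(c(1.0, 1.2, 0.8)),
               tolerance = 1e-12)
  # against stats::t.test as an independent reference
  expect_equal(r$p_value, t.test(c(1.0, 1.2, 0.8))$p.value,
               tolerance = 1e-12)

  rz <- one_sample_test(c(0.5, 0.5, 0.5))
  expect_equal(rz$p_value, 0)
  expect_true(rz$zero_variance)

  expect_true(one_sample_test(c(1, 2))$excluded)
  expect_false(one_sample_test(c(1, 2), min_replicates = 2)$excluded)
})

test_that("two-sample t-test: degenerate cases and oracle equivalence", {
  same <- two_sample_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  degen <- two_sample_test(c(1, 1, 1), c(0, 0, 0))
  expect_equal(degen$p_value, 0)
  expect_true(degen$zero_variance)

  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1), mean = runif(1, -1, 1))
    expect_equal(two_sample_test(x, y)$p_value,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(two_sample_test(x, y, welch = TRUE)$p_value,
                 t.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized whole-table tests equal the scalar operations", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 60,
                                               frac_regulated = 0.3,
                                               seed = 15))
  tab <- sim$proteins
  tab$ml_log2_r2[1:5] <- NA  # exercise missingness
  res <- test_ratio_table(tab)
  ml <- as.matrix(tab[, grep("^ml_log2", names(tab))])
  hl <- as.matrix(tab[, grep("^hl_log2", names(tab))])
  for (i in c(1, 3, 17, 60)) {
    r1 <- subset(res, contrast == "1d_vs_ctrl" &
                   protein_id == tab$protein_id[i])
    sc <- one_sample_test(ml[i, ])
    expect_equal(r1$p_value, sc$p_value)
    expect_equal(r1$excluded, sc$excluded)
    r3 <- subset(res, contrast == "3d_vs_1d" &
                   protein_id == tab$protein_id[i])
    sc2 <- two_sample_test(hl[i, ], ml[i, ])
    expect_equal(r3$p_value, sc2$p_value)
  }
})

test_that("negating all ratios flips direction and preserves p-values", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 80,
                                               frac_regulated = 0.4,
                                               seed = 16))
  tab <- sim$proteins
  neg <- tab
  ratio_cols <- grep("log2_r", names(tab))
  neg[, ratio_cols] <- -tab[, ratio_cols]
  res <- apply_regulation_filters(test_ratio_table(tab))
  res_neg <- apply_regulation_filters(test_ratio_table(neg))
  expect_equal(res$volcano$p_value, res_neg$volcano$p_value,
               tolerance = 1e-12)
  expect_identical(res$volcano$significant, res_neg$volcano$significant)
  sig <- res$volcano$significant
  expect_identical(res$volcano$direction[sig],
                   c(up = "down", down = "up")[res_neg$volcano$direction[sig]],
                   ignore_attr = TRUE)
})

test_that("regulation filter boundaries are as stated", {
  res <- data.frame(protein_id = c("a", "b", "c"), gene = c("A", "B", "C"),
                    contrast = "1d_vs_ctrl",
                    n = 3,
                    mean_log2 = c(0, log2(1.5), log2(1.49)),
                    fold_change = c(1, 1.5, 1.49),
                    p_value = c(0.001, 0.01, 0.01),
                    bh_adjusted_p = NA, zero_variance = FALSE,
                    excluded = FALSE)
  out <- apply_regulation_filters(res)
  expect_identical(out$volcano$significant, c(FALSE, TRUE, FALSE))
  expect_identical(out$union, "b")
})

test_that("union counting is by unique protein id", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 300,
                                               frac_regulated = 0.2,
                                               noise_sd = 0.15, seed = 17))
  out <- apply_regulation_filters(test_ratio_table(sim$proteins))
  n_sets <- sum(vapply(out$sets, nrow, integer(1)))
  expect_lte(length(out$union), n_sets)
  expect_false(any(duplicated(out$union)))
})

test_that("planted regulation is recovered with high sensitivity, low FDR", {
  # 5% regulated at |log2 FC| = 1, sd 0.1: scaled to 10 sims to stay in
  # budget; per-sim sensitivity >= 0.95 and FDR <= 0.1
  for (s in 1:10) {
    sim <- simulate_proteome(proteome_sim_config(
      n_proteins = 400, frac_regulated = 0.05,
      effect_log2fc_range = c(1, 1), noise_sd = 0.1, seed = 100 + s))
    out <- apply_regulation_filters(test_ratio_table(sim$proteins))
    called <- out$union
    truth <- sim$truth$protein_id[sim$truth$is_planted]
    sens <- length(intersect(called, truth)) / length(truth)
    fdr <- if (length(called)) 1 - length(intersect(called, truth)) /
      length(called) else 0
    expect_gte(sens, 0.95)
    expect_lte(fdr, 0.1)
  }
})

test_that("phosphosite localization filter: boundary, saturation, errors", {
  sites <- data.frame(protein_id = paste0("P", 1:4),
                      site_id = paste0("s", 1:4),
                      localization_probability = c(0.74, 0.75, 1.0, 0.2))
  kept <- filter_phosphosites(sites)
  expect_identical(kept$site_id, c("s2", "s3"))
  expect_equal(attr(kept, "retention"), 0.5)

  all1 <- sites
  all1$localization_probability <- 1.0
  expect_equal(attr(filter_phosphosites(all1), "retention"), 1)

  bad <- sites
  bad$localization_probability[1] <- 1.2
  expect_error(filter_phosphosites(bad), "\\[0, 1\\]")
})
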