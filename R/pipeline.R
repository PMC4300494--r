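# End-to-end orchestration: counts -> per-arm differential tests at both
# timepoints -> hairpin selection -> dual-screen gene hits -> optional
# proteomic evidence integration; and the proteome branch
# (tests -> filters -> enrichment).  Intermediate results are plain TSV so
# any stage can be re-run independently.

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  path <- file.path(out_dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

build_manifest <- function(stage, params, seeds, files) {
  files <- files[!vapply(files, is.null, logical(1))]
  list(
    stage = stage,
    package = "sensitizeR",
    version = as.character(packageVersion("sensitizeR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    seeds = seeds,
    outputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
}

#' Run the full screen arm of the pipeline
#'
#' For each drug arm: differential depletion tests at day 7 and day 4
#' (treated vs DMSO), the two-timepoint hairpin filter cascade, the
#' dual-screen hairpin intersection and gene-level hit calling.
#'
#' @param cm a [count_matrix()] (or counts TSV path, with `samples`).
#' @param lib a [hairpin_library()] (or TSV path).
#' @param samples a [sample_sheet()] or TSV path, required when `cm` is a
#'   path.
#' @param arms the two treated arms to analyze (exactly two for gene-hit
#'   intersection).
#' @param fp a [filter_params()].
#' @param sharing dispersion sharing mode.
#' @param allow_missing_day4 see [select_depleted_hairpins()].
#' @param regulated optional regulated-protein table (see
#'   [integrate_evidence()]).
#' @param regulator_map optional regulator map (data.frame or TSV path).
#' @param out_dir optional directory for stage TSVs plus a JSON manifest.
#' @return list with `differential` (per arm x day tables), `hit_sets`,
#'   `shared_hairpins`, `gene_hits` and `manifest`.
#' @export
run_screen_pipeline <- function(cm, lib, samples = NULL,
                                arms = c("PLX", "SCH"),
                                fp = filter_params(), sharing = "max",
                                allow_missing_day4 = FALSE,
                                regulated = NULL, regulator_map = NULL,
                                out_dir = NULL) {
  if (is.character(lib)) lib <- read_hairpin_library(lib)
  if (is.character(cm)) {
    if (is.null(samples)) stop("samples sheet required when counts is a path")
    cm <- read_counts(cm, samples, lib = lib)
  }
  if (length(arms) != 2) stop("gene-hit calling needs exactly two arms")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  sf <- estimate_size_factors(cm)
  files <- list()
  differential <- list()
  hit_sets <- list()
  for (arm in arms) {
    for (d in c(7L, 4L)) {
      key <- sprintf("%s_day%d", arm, d)
      tab <- tryCatch(
        screen_differential(
          cm,
          numerator = list(condition = "treated", treatment = arm, day = d),
          denominator = list(condition = "DMSO", day = d),
          sf = sf, sharing = sharing, lib = lib),
        error = function(e) stop("stage screen_differential[", key, "]: ",
                                 conditionMessage(e), call. = FALSE))
      differential[[key]] <- tab
      files[[key]] <- write_stage_tsv(tab, out_dir,
                                      sprintf("differential_%s.tsv", key))
    }
    hit_sets[[arm]] <- select_depleted_hairpins(
      differential[[sprintf("%s_day7", arm)]],
      differential[[sprintf("%s_day4", arm)]],
      fp = fp, screen = arm, allow_missing_day4 = allow_missing_day4)
    files[[paste0("hits_", arm)]] <-
      write_stage_tsv(hit_sets[[arm]], out_dir,
                      sprintf("hairpin_hits_%s.tsv", arm))
  }
  shared <- intersect_screens(hit_sets[[arms[1]]], hit_sets[[arms[2]]])
  gene_hits <- call_gene_hits(hit_sets[[arms[1]]], hit_sets[[arms[2]]],
                              lib, fp)
  if (!is.null(regulated) && !is.null(regulator_map)) {
    gene_hits <- integrate_evidence(gene_hits, regulated, regulator_map)
  }
  files$gene_hits <- write_stage_tsv(gene_hits, out_dir, "gene_hits.tsv")
  manifest <- build_manifest(
    "screen", params = c(unclass(fp), list(arms = arms, sharing = sharing)),
    seeds = NULL, files = files)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(differential = differential, hit_sets = hit_sets,
       shared_hairpins = shared, gene_hits = gene_hits,
       size_factors = sf, manifest = manifest)
}

#' Run the proteome arm of the pipeline
#'
#' Differential tests over the three contrasts, the fold-change/p filter
#' cascade, phosphosite localization filtering, and hypergeometric GO
#' enrichment of the regulated set against the quantified background.
#'
#' @param proteins native-layout ratio table (or TSV path).
#' @param phospho optional phosphosite table (or TSV path).
#' @param terms optional term map (named list or TSV path) for enrichment.
#' @param fc_min,p_max regulation filter thresholds.
#' @param min_prob phosphosite localization threshold.
#' @param min_replicates,welch test options.
#' @param out_dir optional output directory.
#' @return list with `protein_results`, `protein_filtered` (volcano, sets,
#'   union, regulated), `phospho_results`, `phospho_filtered`,
#'   `phospho_retention`, `enrichment` and `manifest`.
#' @export
run_proteome_pipeline <- function(proteins, phospho = NULL, terms = NULL,
                                  fc_min = 1.5, p_max = 0.05,
                                  min_prob = 0.75, min_replicates = 3,
                                  welch = FALSE, out_dir = NULL) {
  if (is.character(proteins)) proteins <- load_ratio_table(proteins)
  if (is.character(phospho)) phospho <- read.delim(phospho)
  if (is.character(terms)) terms <- read_term_map(terms)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- list()
  prot_res <- test_ratio_table(proteins, min_replicates = min_replicates,
                               welch = welch)
  prot_filt <- apply_regulation_filters(prot_res, fc_min = fc_min,
                                        p_max = p_max)
  files$protein_volcano <- write_stage_tsv(prot_filt$volcano, out_dir,
                                           "protein_volcano.tsv")

  phospho_res <- NULL
  phospho_filt <- NULL
  retention <- NA_real_
  if (!is.null(phospho)) {
    localized <- filter_phosphosites(phospho, min_prob = min_prob)
    retention <- attr(localized, "retention")
    phospho_res <- test_ratio_table(localized, id_col = "site_id",
                                    min_replicates = min_replicates,
                                    welch = welch)
    phospho_filt <- apply_regulation_filters(phospho_res, fc_min = fc_min,
                                             p_max = p_max,
                                             id_col = "site_id")
    files$phospho_volcano <- write_stage_tsv(phospho_filt$volcano, out_dir,
                                             "phospho_volcano.tsv")
  }

  enr <- NULL
  if (!is.null(terms) && length(prot_filt$union)) {
    background <- unique(proteins$gene)
    target <- unique(prot_filt$regulated$gene)
    enr <- hypergeometric_enrichment(target, background, terms)
    files$enrichment <- write_stage_tsv(enr, out_dir, "enrichment.tsv")
  }
  manifest <- build_manifest(
    "proteome",
    params = list(fc_min = fc_min, p_max = p_max, min_prob = min_prob,
                  min_replicates = min_replicates, welch = welch),
    seeds = NULL, files = files)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(protein_results = prot_res, protein_filtered = prot_filt,
       phospho_results = phospho_res, phospho_filtered = phospho_filt,
       phospho_retention = retention, enrichment = enr,
       manifest = manifest)
}

#' Run the whole pipeline from a YAML configuration
#'
#' The config mirrors the function arguments: a `screen:` block (`counts`,
#' `library`, `samples`, `arms`, `filter:` thresholds) and/or a
#' `proteome:` block (`proteins`, `phospho`, `terms`, thresholds), plus
#' `out_dir`.  A `screen: simulate:` (or `proteome: simulate:`) block with
#' generator parameters replaces file inputs with synthetic data.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return list with `screen` and/or `proteome` results.
#' @export
run_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir
  res <- list()
  if (!is.null(cfg$screen)) {
    sc <- cfg$screen
    fp <- do.call(filter_params, if (is.null(sc$filter)) list() else
      sc$filter)
    if (!is.null(sc$simulate)) {
      sim_args <- sc$simulate
      if (!is.null(sim_args$planted_sensitizers)) {
        sim_args$planted_sensitizers <-
          as.data.frame(do.call(rbind.data.frame, sim_args$planted_sensitizers))
      }
      sim <- simulate_screen(do.call(screen_sim_config, sim_args))
      cm <- sim$counts
      lib <- sim$library
    } else {
      lib <- read_hairpin_library(sc$library)
      cm <- read_counts(sc$counts, read_sample_sheet(sc$samples), lib = lib)
    }
    res$screen <- run_screen_pipeline(
      cm, lib, arms = if (is.null(sc$arms)) c("PLX", "SCH") else
        unlist(sc$arms),
      fp = fp,
      out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "screen"))
  }
  if (!is.null(cfg$proteome)) {
    pc <- cfg$proteome
    if (!is.null(pc$simulate)) {
      sim <- simulate_proteome(do.call(proteome_sim_config, pc$simulate))
      proteins <- sim$proteins
      phospho <- sim$phospho
    } else {
      proteins <- load_ratio_table(
        pc$proteins,
        dialect = if (is.null(pc$dialect)) "native" else pc$dialect)
      phospho <- if (is.null(pc$phospho)) NULL else read.delim(pc$phospho)
    }
    args <- list(proteins = proteins, phospho = phospho,
                 terms = pc$terms,
                 out_dir = if (is.null(out_dir)) NULL else
                   file.path(out_dir, "proteome"))
    for (nm in c("fc_min", "p_max", "min_prob", "min_replicates")) {
      if (!is.null(pc[[nm]])) args[[nm]] <- pc[[nm]]
    }
    res$proteome <- do.call(run_proteome_pipeline, args)
  }
  res
}
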