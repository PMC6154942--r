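# End-to-end orchestration: simulate -> validate -> diversity -> saturate
# -> associate -> index -> grid, with per-stage derived seeds, TSV
# intermediates, a manifest and a human-readable report.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions of population-scale microbiome
#' studies of metabolic disease: rarefaction depth 10,000 reads, 10%
#' prevalence filter, FDR 0.05, and age, gender, region and Bristol stool
#' scale as confounders. The configuration round-trips through a YAML file
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n Cohort size to simulate.
#' @param n_otus,n_signal OTU counts for the simulated table.
#' @param depth Rarefaction depth (reads/sample).
#' @param prevalence Minimum prevalence fraction.
#' @param fdr False-discovery-rate level.
#' @param confounders Confounder columns.
#' @param factors Factors to test.
#' @param weight_mode Index weight mode, see [compute_mets_index()].
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param saturation_sizes Subsample sizes for the saturation stage (NULL
#'   skips the stage).
#' @param saturation_replicates,n_perm Saturation stage settings.
#' @return A list of class `gutmets_pipeline_config`.
#' @export
pipeline_config <- function(n = 500, n_otus = 300, n_signal = 60,
                            depth = 10000, prevalence = 0.10, fdr = 0.05,
                            confounders = c("age", "gender", "region",
                                            "bristol"),
                            factors = c("mets", "waist", "sbp", "dbp", "tg",
                                        "hdl", "fbg"),
                            weight_mode = "beta_logq", seed = 1,
                            saturation_sizes = c(100, 200, 400),
                            saturation_replicates = 10, n_perm = 199) {
  structure(as.list(environment()), class = "gutmets_pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `gutmets_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

stage_log <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stage, sprintf(...))
  writeLines(msg, con)
  rlang::inform(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate, validate, diversity, saturate,
#' associate, index, grid), writing every intermediate as TSV into
#' `out_dir` together with a JSON manifest (parameters, derived seeds, file
#' hashes) and a short report. Re-running with the same configuration
#' reproduces byte-identical numeric outputs. A stage failure halts the run
#' with the stage name; partial outputs are retained.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "gutmets_pipeline_config")) {
    abort_invalid_config("`config` must come from pipeline_config().")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  results <- list()
  current_stage <- "setup"
  run_stage <- function(stage, expr) {
    current_stage <- stage
    tryCatch(expr, error = function(e) {
      abort_gutmets(sprintf("pipeline stage `%s` failed: %s", stage,
                            conditionMessage(e)),
                    "gutmets_stage_error", stage = stage, parent = e)
    })
  }
  cfg <- config

  run_stage("simulate", {
    stage_log(con, "simulate",
              "n=%d, n_otus=%d, n_signal=%d, depth=%d, seed=%d",
              cfg$n, cfg$n_otus, cfg$n_signal, cfg$depth, cfg$seed)
    sc <- mets_scenario(n = cfg$n, n_otus = cfg$n_otus,
                        n_signal = cfg$n_signal, depth = cfg$depth,
                        seed = cfg$seed, tree = TRUE)
    results$scenario <- sc
    write_cohort(sc$cohort, file.path(out_dir, "cohort.tsv"))
    write_otu_table(sc$table, file.path(out_dir, "otu_table.tsv"))
    write_effects(sc$effects, file.path(out_dir, "ground_truth.tsv"))
    write_newick(sc$tree, file.path(out_dir, "tree.nwk"))
  })

  run_stage("validate", {
    validate_dataset(results$scenario$table, results$scenario$cohort,
                     results$scenario$tree)
    stage_log(con, "validate", "table/cohort/tree consistent")
  })

  run_stage("diversity", {
    sc <- results$scenario
    rare <- rarefy(sc$table, min(cfg$depth, min(rowSums(sc$table$counts))),
                   seed = derive_seed(cfg$seed, "rarefy"))
    div <- alpha_diversity(rare, sc$tree)
    results$diversity <- div
    results$diversity_tests <- diversity_comparison(div, sc$cohort)
    readr::write_tsv(div, file.path(out_dir, "alpha_diversity.tsv"))
    readr::write_tsv(results$diversity_tests,
                     file.path(out_dir, "diversity_tests.tsv"))
    stage_log(con, "diversity", "computed for %d samples", nrow(div))
  })

  run_stage("saturate", {
    if (is.null(cfg$saturation_sizes)) {
      stage_log(con, "saturate", "skipped (no sizes configured)")
    } else {
      sc <- results$scenario
      sat <- saturation_curve(sc$table, sc$cohort$mets,
                              sizes = cfg$saturation_sizes,
                              replicates = cfg$saturation_replicates,
                              n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed, "saturate"))
      results$saturation <- sat
      readr::write_tsv(sat$draws, file.path(out_dir, "saturation.tsv"))
      stage_log(con, "saturate", "saturation size: %s",
                ifelse(is.na(sat$saturation_size), "not reached",
                       sat$saturation_size))
    }
  })

  run_stage("associate", {
    sc <- results$scenario
    filtered <- prevalence_filter(sc$table, cfg$prevalence)
    records <- fit_associations(filtered, sc$cohort, factors = cfg$factors,
                                confounders = cfg$confounders,
                                fdr = cfg$fdr)
    results$filtered <- filtered
    results$associations <- records
    write_associations(records, file.path(out_dir, "associations.tsv"))
    net <- summarize_network(records)
    results$network <- net
    readr::write_tsv(net$per_taxon, file.path(out_dir, "network_taxa.tsv"))
    readr::write_tsv(net$per_factor, file.path(out_dir, "network_factors.tsv"))
    stage_log(con, "associate", "%d significant of %d records",
              sum(records$significant), nrow(records))
  })

  run_stage("index", {
    sc <- results$scenario
    idx <- compute_mets_index(results$filtered, results$associations,
                              weight_mode = cfg$weight_mode)
    results$index <- idx
    readr::write_tsv(tibble::as_tibble(idx)[c("sample_id", "mets_index")],
                     file.path(out_dir, "mets_index.tsv"))
    val <- stratified_validation(idx, sc$cohort)
    results$index_validation <- val
    readr::write_tsv(val, file.path(out_dir, "index_validation.tsv"))
    stage_log(con, "index", "index over %d OTUs", nrow(tidy(idx)))
  })

  run_stage("grid", {
    sc <- results$scenario
    grid <- additive_risk_grid(results$index, sc$cohort)
    results$grid <- grid
    readr::write_tsv(grid$cells[c("cell", "index_q", "sedentary_q", "n",
                                  "n_mets", "prevalence")],
                     file.path(out_dir, "risk_grid.tsv"))
    if (!is.null(grid$pairwise)) {
      readr::write_tsv(grid$pairwise, file.path(out_dir, "risk_grid_tests.tsv"))
    }
    if (!is.null(grid$occupancy)) {
      readr::write_tsv(grid$occupancy,
                       file.path(out_dir, "risk_grid_occupancy.tsv"))
    }
    stage_log(con, "grid", "corner contrast %.1f%% vs %.1f%%",
              grid$corners$high_high, grid$corners$low_low)
  })

  # Manifest: configuration, derived seeds and hashes of every output.
  outputs <- sort(setdiff(list.files(out_dir), c("manifest.json",
                                                 "pipeline.log",
                                                 "report.txt")))
  manifest <- list(
    package = "gutmets",
    version = as.character(utils::packageVersion("gutmets")),
    config = unclass(cfg),
    stage_seeds = list(
      cohort = derive_seed(cfg$seed, "cohort"),
      profile = derive_seed(cfg$seed, "profile"),
      effects = derive_seed(cfg$seed, "effects"),
      counts = derive_seed(cfg$seed, "counts"),
      rarefy = derive_seed(cfg$seed, "rarefy"),
      saturate = derive_seed(cfg$seed, "saturate")
    ),
    files = as.list(tools::md5sum(file.path(out_dir, outputs)) |>
                      setNames(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  report <- c(
    "gutmets pipeline report",
    sprintf("cohort: n=%d, MetS prevalence %.1f%%", cfg$n,
            100 * mean(results$scenario$cohort$mets)),
    sprintf("OTUs: %d simulated, %d after %.0f%% prevalence filter",
            cfg$n_otus, ncol(results$filtered$counts),
            100 * cfg$prevalence),
    sprintf("associations: %d significant of %d at q <= %g",
            sum(results$associations$significant),
            nrow(results$associations), cfg$fdr),
    sprintf("network totals: %d associations (%d- / %d+ disorder valence)",
            results$network$totals$n_associations,
            results$network$totals$n_negative,
            results$network$totals$n_positive),
    sprintf("risk grid corners: high/high %.1f%%, low/low %.1f%%",
            results$grid$corners$high_high, results$grid$corners$low_low)
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(results = results, manifest = manifest))
}
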