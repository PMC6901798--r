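#' Declarative configuration of a full discovery-to-validation run
#'
#' Collects every tunable of the end-to-end pipeline in one validated object.
#' Stage seeds are derived deterministically from `master_seed` and the stage
#' name, so one integer reproduces the whole run.
#'
#' @param simulation A [simulation_config()] describing the discovery cohorts.
#'   The configured samples are split evenly over `n_batches` separately
#'   simulated cohorts (each internally single-batch, with its own batch
#'   shift), which [merge_datasets()] then relabels by cohort — mirroring
#'   multi-series discovery data.
#' @param validation_n_tumor,validation_n_normal Shape of the independently
#'   simulated validation cohort (defaults 458 / 34, a heavily imbalanced
#'   450k-style cohort).
#' @param logfc_threshold,adjp_threshold DMP calling thresholds (1.0, 0.05).
#' @param corr_threshold,folds,trees,elimination_fraction Panel-selection
#'   tunables, see [selection_config()].
#' @param test_fraction Validation held-out fraction (0.2).
#' @param master_seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = default_recovery_scenario(),
                            validation_n_tumor = 458L,
                            validation_n_normal = 34L,
                            logfc_threshold = 1.0,
                            adjp_threshold = 0.05,
                            corr_threshold = 0.7,
                            folds = 10L,
                            trees = 500L,
                            elimination_fraction = 0.2,
                            test_fraction = 0.2,
                            master_seed = 1L) {
  validate_simulation_config(simulation)
  # validates folds/trees/corr/elimination before any stage runs
  sel <- selection_config(corr_threshold = corr_threshold, folds = folds,
                          trees = trees,
                          elimination_fraction = elimination_fraction,
                          seed = master_seed)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    mp_abort("`test_fraction` must lie in (0, 1)", "mp_config_error")
  }
  if (!is.numeric(logfc_threshold) || logfc_threshold < 0) {
    mp_abort("`logfc_threshold` must be >= 0", "mp_config_error")
  }
  if (!is.numeric(adjp_threshold) || adjp_threshold <= 0 || adjp_threshold > 1) {
    mp_abort("`adjp_threshold` must lie in (0, 1]", "mp_config_error")
  }
  for (field in c("validation_n_tumor", "validation_n_normal")) {
    v <- get(field)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      mp_abort(sprintf("`%s` must be an integer >= 1", field),
               "mp_config_error")
    }
  }
  structure(list(simulation = simulation,
                 validation_n_tumor = as.integer(validation_n_tumor),
                 validation_n_normal = as.integer(validation_n_normal),
                 logfc_threshold = logfc_threshold,
                 adjp_threshold = adjp_threshold,
                 selection = sel,
                 test_fraction = test_fraction,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Deterministic per-stage seed
#'
#' Pure function of the master seed and the stage name (a character hash),
#' kept inside the 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) + 131 * h) %% (.Machine$integer.max - 1L))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the whole discovery-to-validation pipeline
#'
#' Executes, in order: cohort simulation, merge by common probes, beta-to-M
#' transform and batch adjustment, moderated-t differential methylation with
#' BH adjustment and threshold calling, two-means binarization of the called
#' probes, RFE-ranked greedy panel construction with CV model choice, and
#' external validation of the chosen panel on a freshly simulated imbalanced
#' cohort (re-binarize, stratified 80/20 split, ROSE rebalancing of the
#' training side, fresh forest, untouched test set). All randomness flows
#' from the config's master seed through [stage_seed()], so a rerun with the
#' same config reproduces byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written there (TSV/JSON) together with `manifest.json` recording the
#'   config, the derived seeds and the md5 of every file.
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, a list with the per-stage objects: `cohorts`, `merged`,
#'   `adjusted`, `dmp_table`, `dmps`, `features`, `panel`, `validation`
#'   (cohort sheet + `report`), `ground_truth` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    mp_abort("`config` must come from pipeline_config()", "mp_config_error")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  ms <- config$master_seed
  sim <- config$simulation

  # -- simulate: one cohort per configured batch, each single-batch ---------
  n_cohorts <- sim$n_batches
  split_counts <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + as.integer(seq_len(k) <= extra)
  }
  tum <- split_counts(sim$n_tumor, n_cohorts)
  nor <- split_counts(sim$n_normal, n_cohorts)
  say("simulate: %d cohort(s)", n_cohorts)
  cohorts <- vector("list", n_cohorts)
  names(cohorts) <- sprintf("cohort%d", seq_len(n_cohorts))
  ground_truth <- NULL
  for (i in seq_len(n_cohorts)) {
    cfg_i <- sim
    cfg_i$n_tumor <- tum[i]
    cfg_i$n_normal <- nor[i]
    cfg_i$n_batches <- 1L
    cfg_i$seed <- stage_seed(ms, "simulate") + i
    cohorts[[i]] <- simulate_cohort(cfg_i)
    ground_truth <- cohorts[[i]]$ground_truth  # identical across cohorts
  }

  # -- merge ----------------------------------------------------------------
  say("merge")
  if (n_cohorts >= 2L) {
    merged <- merge_datasets(lapply(cohorts, `[[`, "matrix"),
                             lapply(cohorts, `[[`, "sheet"))
  } else {
    one <- cohorts[[1L]]
    sheet <- one$sheet
    sheet$batch <- names(cohorts)[1L]
    merged <- list(matrix = one$matrix, sheet = sheet)
  }

  # -- adjust ---------------------------------------------------------------
  say("adjust")
  m_space <- beta_to_m(merged$matrix)
  adjusted <- batch_adjust(m_space, merged$sheet)

  # -- dmp ------------------------------------------------------------------
  say("dmp")
  dmp_table <- dmp_analysis(adjusted$matrix, merged$sheet)
  dmps <- call_dmps(dmp_table, config$logfc_threshold, config$adjp_threshold)
  if (nrow(dmps) == 0L) {
    mp_abort("stage dmp: no probe passed the DMP thresholds", "mp_stage_error")
  }

  # -- binarize -------------------------------------------------------------
  say("binarize: %d called probes", nrow(dmps))
  features <- binarize_matrix(adjusted$matrix, dmps$probe_id)

  # -- select ---------------------------------------------------------------
  say("select")
  sel <- config$selection
  sel$seed <- stage_seed(ms, "select")
  sheet <- align_sheet(adjusted$matrix, merged$sheet)
  panel <- build_panel(features, sheet$group, sel)

  # -- validate -------------------------------------------------------------
  say("validate: %d/%d cohort", config$validation_n_tumor,
      config$validation_n_normal)
  vcfg <- sim
  vcfg$n_tumor <- config$validation_n_tumor
  vcfg$n_normal <- config$validation_n_normal
  vcfg$n_batches <- 1L
  vcfg$seed <- stage_seed(ms, "validate_simulate")
  vcohort <- simulate_cohort(vcfg)
  vmatrix <- beta_to_m(vcohort$matrix)
  report <- validate_external(vmatrix, vcohort$sheet, panel,
                              test_fraction = config$test_fraction,
                              trees = config$selection$trees,
                              seed = stage_seed(ms, "validate"))

  result <- list(cohorts = cohorts, merged = merged, adjusted = adjusted,
                 dmp_table = dmp_table, dmps = dmps, features = features,
                 panel = panel,
                 validation = list(sheet = vcohort$sheet, report = report),
                 ground_truth = ground_truth, manifest = NULL)

  if (!is.null(out_dir)) {
    result$manifest <- write_run_artifacts(result, config, out_dir)
  }
  invisible(result)
}

# Serialise every stage artifact plus a manifest with config, seeds and md5s.
write_run_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_matrix(result$merged$matrix, p("merged_matrix.tsv"))
  write_sample_sheet(result$merged$sheet, p("merged_sheet.tsv"))
  write_matrix(result$adjusted$matrix, p("adjusted_matrix.tsv"))
  write_dmp_table(result$dmp_table, p("dmp_table.tsv"))
  write_dmp_table(result$dmps, p("dmps_called.tsv"))
  utils::write.table(
    data.frame(result$features$values, check.names = FALSE),
    p("binary_features.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(result$panel$trace, p("panel_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel <- result$panel
  write_json_artifact(list(
    probes = panel$probes,
    size = panel$size,
    cv_accuracy = panel$cv_accuracy,
    cv_kappa = panel$cv_kappa,
    splits = panel$splits,
    trace = panel$trace,
    candidate_order = panel$candidate_order,
    thresholds = list(corr = panel$config$corr_threshold,
                      logfc = config$logfc_threshold,
                      adjp = config$adjp_threshold),
    seeds = list(select = panel$config$seed)
  ), p("panel.json"))
  rep <- result$validation$report
  write_json_artifact(unclass(rep), p("validation_report.json"))

  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  write_json_artifact(strip_classes(config), p("config.json"))
  files <- c("merged_matrix.tsv", "merged_sheet.tsv", "adjusted_matrix.tsv",
             "dmp_table.tsv", "dmps_called.tsv", "binary_features.tsv",
             "panel_trace.tsv", "panel.json", "validation_report.json",
             "config.json")
  md5 <- tools::md5sum(vapply(files, p, character(1)))
  names(md5) <- files
  manifest <- list(
    package = "methpanel",
    version = as.character(utils::packageVersion("methpanel")),
    master_seed = config$master_seed,
    stage_seeds = list(simulate = stage_seed(config$master_seed, "simulate"),
                       select = stage_seed(config$master_seed, "select"),
                       validate_simulate = stage_seed(config$master_seed,
                                                      "validate_simulate"),
                       validate = stage_seed(config$master_seed, "validate")),
    files = as.list(md5)
  )
  write_json_artifact(manifest, p("manifest.json"))
  manifest
}
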