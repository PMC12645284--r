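# End-to-end pipeline runner: wires the stages together under one config and
# records a manifest (config, package version, seed, input digests) so a run
# can be reproduced exactly.

#' Run configuration for the pipeline
#'
#' @param stages character vector among `"build_trimers"`, `"benchmark"`,
#'   `"ad"`, `"explain"`; executed in dependency order.
#' @param dataset path to a dataset CSV mirroring the study table (default:
#'   packaged 48-polymer table).
#' @param registry path to a monomer registry CSV (default: packaged).
#' @param out_dir output directory for artefacts and the manifest.
#' @param seed integer seed.
#' @param algorithm,features benchmark settings (defaults `"rf"`,
#'   `"fingerprint"`).
#' @param grid a [hyper_grid()].
#' @param ad an [ad_config()].
#' @return a `run_config` object.
#' @export
run_config <- function(stages = c("build_trimers", "benchmark", "ad", "explain"),
                       dataset = NULL, registry = NULL, out_dir = tempfile("polybiodeg_run_"),
                       seed = 1, algorithm = "rf", features = "fingerprint",
                       grid = hyper_grid(), ad = ad_config()) {
  known <- c("build_trimers", "benchmark", "ad", "explain")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "polybiodeg_usage_error")
  }
  structure(list(stages = known[known %in% stages], dataset = dataset,
                 registry = registry, out_dir = out_dir, seed = seed,
                 algorithm = algorithm, features = features, grid = grid,
                 ad = ad),
            class = "run_config")
}

#' Execute a pipeline run
#'
#' Stages run in dependency order; every run writes `manifest.json` (config,
#' package version, seed, input digests) plus per-stage artefacts
#' (`trimers.csv`, `benchmark.json`, `ad_report.csv`, `feature_report.csv`)
#' into the run directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of in-memory stage results; artefact paths in
#'   `$files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset_path <- config$dataset %||%
    system.file("extdata", "table1.csv", package = "polybiodeg")
  registry_path <- config$registry %||%
    system.file("extdata", "monomers.csv", package = "polybiodeg")
  manifest <- list(
    package = "polybiodeg",
    version = as.character(utils::packageVersion("polybiodeg")),
    seed = config$seed,
    stages = config$stages,
    inputs = list(dataset = unname(tools::md5sum(dataset_path)),
                  registry = unname(tools::md5sum(registry_path))),
    settings = list(algorithm = config$algorithm, features = config$features)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results <- list(files = character(0))

  data <- if (is.null(config$dataset)) load_table1() else {
    as_tibble(read.csv(dataset_path, stringsAsFactors = FALSE, na.strings = "n.d.")) %>%
      mutate(label = .data$biodegradable %in% c("Yes", "TRUE", "1", "yes"))
  }
  registry <- load_monomer_registry(if (is.null(config$registry)) NULL else registry_path)

  trimers <- build_dataset_trimers(data, registry)
  if ("build_trimers" %in% config$stages) {
    f <- file.path(config$out_dir, "trimers.csv")
    utils::write.csv(trimers %>% select("id", "trimer_smiles"), f, row.names = FALSE)
    results$files <- c(results$files, f)
    results$trimers <- trimers
  }
  if ("benchmark" %in% config$stages) {
    cv <- nested_cv(trimers, config$algorithm, config$features, config$grid,
                    seed = config$seed)
    f <- file.path(config$out_dir, "benchmark.json")
    jsonlite::write_json(as.list(glance(cv)), f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    results$files <- c(results$files, f)
    results$benchmark <- cv
  }
  needs_model <- any(c("ad", "explain") %in% config$stages)
  if (needs_model) {
    fm <- final_model(trimers, config$algorithm, config$features, config$grid,
                      seed = config$seed)
    results$final_model <- fm
  }
  if ("ad" %in% config$stages) {
    ad <- fit_ad(fm$fp$matrix, config$ad)
    rel <- reliability_scores(fm$fp$matrix, config$ad, mode = "loo")
    rep <- gate(predict_prob(fm$model, fm$feature_matrix), fm$fp$matrix, ad)
    rep$reliability_score <- rel$reliability_score
    rep$similarity_group <- rel$similarity_group
    f <- file.path(config$out_dir, "ad_report.csv")
    utils::write.csv(rep, f, row.names = FALSE)
    results$files <- c(results$files, f)
    results$ad_report <- rep
  }
  if ("explain" %in% config$stages) {
    if (config$algorithm != "rf") {
      abort("Shapley explanation is available for the random-forest model",
            class = "polybiodeg_usage_error")
    }
    sh <- shap_values(fm)
    rep <- feature_report(sh)
    f <- file.path(config$out_dir, "feature_report.csv")
    utils::write.csv(tidy(rep) %>% select(-"fragments"), f, row.names = FALSE)
    results$files <- c(results$files, f)
    results$shap <- sh
    results$feature_report <- rep
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
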