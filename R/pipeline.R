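#' Default pipeline configuration
#'
#' @param seed master seed propagated to every stage.
#' @param out_dir directory all artifacts are written under.
#' @param sim list of [sim_config()] overrides.
#' @param glm list with `response` (`"VM"`/`"VT"`).
#' @param ensemble list of [ensemble_config()] overrides (scheme, version,
#'   n_iterations, n_trees, ...).
#' @param stages subset of `c("simulate", "features", "glm", "train",
#'   "evaluate")` to run; later stages read the artifacts earlier stages
#'   wrote, so a skipped stage's outputs must already exist in `out_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("nestage-run-"),
                            sim = list(), glm = list(response = "VM"),
                            ensemble = list(scheme = "AGE2", version = "full",
                                            n_iterations = 100, n_trees = 250),
                            stages = c("simulate", "features", "glm",
                                       "train", "evaluate")) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, sim = sim, glm = glm,
         ensemble = ensemble, stages = stages),
    class = "pipeline_config"
  )
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

#' Run the full inference pipeline
#'
#' Executes, in order, the stages `simulate` (synthetic colony ->
#' `nests.csv`, `environment.csv`), `features` (`features.csv`), `glm`
#' (age-only AIC ranking -> `glm_ranking.csv`), `train` (balanced-bootstrap
#' ensemble -> `ensemble_summary.json`, `mismatch_counts.csv`) and
#' `evaluate` (`misclassification_by_year.csv`, `misclassification_by_age.csv`).
#' A `run_metadata.json` header records the seed, a config hash and package
#' version, making reruns auditable; the whole run is deterministic in the
#' master seed.
#'
#' @param config a [pipeline_config()], a list of its arguments, or the
#'   path to a YAML file of them.
#' @return invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) name %in% config$stages
  results <- list(out_dir = config$out_dir)
  fail <- function(name, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  }

  meta <- list(
    seed = config$seed,
    config_hash = fnv1a_hash(paste(deparse(config[c("seed", "sim", "glm",
                                                    "ensemble")]),
                                   collapse = "")),
    package = "nestage",
    version = as.character(utils::packageVersion("nestage")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = config$stages
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if (stage("simulate")) {
    tryCatch({
      sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
      scfg <- do.call(sim_config, sim_args)
      ds <- generate_dataset(scfg)
      write_dataset(ds, config$out_dir)
      results$dataset <- ds
    }, error = function(e) fail("simulate", e))
  }

  ens_defaults <- list(scheme = "AGE2", version = "full",
                       n_iterations = 100, n_trees = 250, seed = config$seed)
  ens_args <- utils::modifyList(ens_defaults, config$ensemble)
  ecfg <- do.call(ensemble_config, ens_args)

  if (stage("features")) {
    tryCatch({
      nests <- utils::read.csv(file.path(config$out_dir, "nests.csv"))
      env_path <- file.path(config$out_dir, "environment.csv")
      environment <- if (file.exists(env_path)) utils::read.csv(env_path)
      feats <- build_feature_table(nests, environment,
                                   version = ens_args$version,
                                   scheme = ecfg$scheme)
      utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      results$features <- feats
    }, error = function(e) fail("features", e))
  }

  # stages after `features` can resume from a features.csv written earlier
  load_features <- function() {
    f <- utils::read.csv(file.path(config$out_dir, "features.csv"))
    if ("Clutch" %in% names(f)) f$Clutch <- factor(f$Clutch, levels = 1:5)
    if ("Year" %in% names(f)) f$Year <- factor(f$Year)
    if ("age_class" %in% names(f)) {
      f$age_class <- factor(f$age_class, levels = ecfg$scheme$labels)
    }
    attr(f, "predictors") <- intersect(version_predictors(ens_args$version),
                                       names(f))
    f
  }

  if (stage("glm")) {
    tryCatch({
      if (is.null(results$features)) results$features <- load_features()
      response <- if (!is.null(config$glm$response)) config$glm$response else "VM"
      rank <- select_age_model(results$features, response = response)
      utils::write.csv(as.data.frame(rank),
                       file.path(config$out_dir, "glm_ranking.csv"),
                       row.names = FALSE)
      results$glm_ranking <- rank
    }, error = function(e) fail("glm", e))
  }

  if (stage("train")) {
    tryCatch({
      if (is.null(results$features)) results$features <- load_features()
      ens <- run_ensemble(results$features, ecfg)
      summary <- list(
        scheme = ecfg$scheme$name, version = ecfg$version,
        n_iterations = ens$n_iterations, n_trees = ecfg$n_trees,
        accuracy = ens$accuracy, sensitivity = ens$sensitivity,
        specificity = ens$specificity,
        gini = as.list(ens$gini_aggregate)
      )
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "ensemble_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(
        data.frame(nest_id = names(ens$mismatch_counts),
                   mismatch_count = as.integer(ens$mismatch_counts)),
        file.path(config$out_dir, "mismatch_counts.csv"), row.names = FALSE)
      results$ensemble <- ens
    }, error = function(e) fail("train", e))
  }

  if (stage("evaluate")) {
    tryCatch({
      nests <- utils::read.csv(file.path(config$out_dir, "nests.csv"))
      ens <- results$ensemble
      rep <- misclassification_report(ens$mismatch_counts, nests,
                                      ens$n_iterations)
      utils::write.csv(rep$per_year,
                       file.path(config$out_dir, "misclassification_by_year.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$per_age,
                       file.path(config$out_dir, "misclassification_by_age.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$per_nest,
                       file.path(config$out_dir, "misclassification_report.csv"),
                       row.names = FALSE)
      results$report <- rep
    }, error = function(e) fail("evaluate", e))
  }
  invisible(results)
}
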