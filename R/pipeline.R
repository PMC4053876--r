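#' Run the full assessment pipeline
#'
#' Wires the stages together over a plain-file artifact directory:
#' `simulate` (synthetic fixture set) -> `train` (one network per
#' pollutant) -> `predict` (concentration grids) -> `iaqi` (individual
#' index grids) -> `paqi` (composite index grid) -> `exposure` (zonal
#' statistics CSV). Any contiguous suffix of stages can be run against
#' precomputed artifacts in `out_dir` — every artifact is a standard
#' plain-text format (ESRI ASCII grid, CSV, JSON), so any stage's inputs
#' can equally come from real data. A `manifest.json` recording the
#' configuration, seeds, package version and artifact checksums is written
#' at the end; deterministic stages reproduce bit-identical artifacts (and
#' manifests) under the same seed.
#'
#' @param out_dir Artifact directory (created if missing).
#' @param config A [sim_config()]; its seed drives every stochastic stage.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param layer_sizes,n_runs,max_iter Training hyperparameters (see
#'   [train_lm()]).
#' @param low_cut,high_cut Composite-index weight cutoffs (see
#'   [modify_weights()]).
#' @param pc_form Per-capita statistic form (see [pc_pm25()]).
#' @param quiet Suppress progress messages?
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         stages = c("simulate", "train", "predict",
                                    "iaqi", "paqi", "exposure"),
                         layer_sizes = NULL, n_runs = 50, max_iter = 100,
                         low_cut = 0.05, high_cut = 0.5,
                         pc_form = "population_product", quiet = FALSE) {
  all_stages <- c("simulate", "train", "predict", "iaqi", "paqi", "exposure")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  pred_names <- c("lat", "lon", "WS", "RH", "SKT", "HPBL", "AOT", "SSA")
  p <- function(f) file.path(out_dir, f)

  run_stage <- function(name, fn) {
    say("stage ", name, " ...")
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(files, stage) {
    missing_f <- files[!file.exists(file.path(out_dir, files))]
    if (length(missing_f)) {
      stop("missing input artifact(s) for stage '", stage, "': ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    }
  }
  warn_stale(out_dir, stages)

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sim <- simulate_all(config)
    for (nm in names(sim$fields)) {
      write_grid(sim$fields[[nm]], p(paste0(nm, ".asc")))
    }
    write_grid(sim$population, p("population.asc"))
    write_zones(sim$zones, p("zones.asc"))
    write_stations(sim$stations_pm25, p("stations_pm25.csv"))
    write_stations(sim$stations_pm10, p("stations_pm10.csv"))
  })

  if ("train" %in% stages) run_stage("train", function() {
    need(c("stations_pm25.csv", "stations_pm10.csv"), "train")
    for (poll in c("pm25", "pm10")) {
      tab <- read_stations(p(paste0("stations_", poll, ".csv")),
                           predictors = pred_names)
      fit <- train_lm(tab, layer_sizes = layer_sizes, n_runs = n_runs,
                      max_iter = max_iter, seed = config$seed)
      write_ann(fit$model, p(paste0("model_", poll, ".json")))
      readr::write_csv(tidy(fit$report), p(paste0("runs_", poll, ".csv")))
      g <- glance(fit$report)
      say(sprintf("  %s: best run %d, validation r = %.3f",
                  toupper(poll), g$best_run, g$best_r))
    }
  })

  if ("predict" %in% stages) run_stage("predict", function() {
    need(c(paste0(pred_names, ".asc"), "model_pm25.json",
           "model_pm10.json"), "predict")
    fields <- stats::setNames(
      lapply(pred_names, function(nm) read_grid(p(paste0(nm, ".asc")),
                                                variable = nm)),
      pred_names)
    for (poll in c("pm25", "pm10")) {
      model <- read_ann(p(paste0("model_", poll, ".json")))
      write_grid(predict_grid(model, fields), p(paste0(poll, "_pred.asc")))
    }
  })

  if ("iaqi" %in% stages) run_stage("iaqi", function() {
    need(c("pm25_pred.asc", "pm10_pred.asc"), "iaqi")
    write_grid(iaqi_grid(read_grid(p("pm25_pred.asc"), "PM2.5"),
                         default_breakpoints("PM2.5")), p("ipm25.asc"))
    write_grid(iaqi_grid(read_grid(p("pm10_pred.asc"), "PM10"),
                         default_breakpoints("PM10")), p("ipm10.asc"))
  })

  if ("paqi" %in% stages) run_stage("paqi", function() {
    need(c("ipm25.asc", "ipm10.asc"), "paqi")
    out <- paqi_grid(list(PM10 = read_grid(p("ipm10.asc"), "IPM10"),
                          PM2.5 = read_grid(p("ipm25.asc"), "IPM2.5")),
                     low_cut = low_cut, high_cut = high_cut)
    write_grid(out, p("paqi.asc"))
  })

  if ("exposure" %in% stages) run_stage("exposure", function() {
    need(c("pm25_pred.asc", "population.asc", "zones.asc"), "exposure")
    rep <- zonal_report(read_grid(p("pm25_pred.asc"), "PM2.5"),
                        read_grid(p("population.asc"), "population"),
                        read_zones(p("zones.asc")), form = pc_form)
    readr::write_csv(tibble::as_tibble(rep), p("exposure.csv"))
  })

  manifest <- list(
    package = "paqr",
    version = as.character(utils::packageVersion("paqr")),
    stages = stages,
    seed = config$seed,
    config = config[setdiff(names(config), "truth")],
    truth_spec = config$truth,
    parameters = list(layer_sizes = layer_sizes, n_runs = n_runs,
                      max_iter = max_iter, low_cut = low_cut,
                      high_cut = high_cut, pc_form = pc_form),
    artifacts = artifact_checksums(out_dir)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", p("manifest.json"))
  invisible(manifest)
}

artifact_checksums <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(as.list(unname(sums)), files)
}

# Pipeline dependency edges used for stale-artifact warnings.
stage_deps <- list(
  train = c("stations_pm25.csv", "stations_pm10.csv"),
  predict = c("model_pm25.json", "model_pm10.json"),
  iaqi = c("pm25_pred.asc", "pm10_pred.asc"),
  paqi = c("ipm25.asc", "ipm10.asc"),
  exposure = c("pm25_pred.asc", "population.asc", "zones.asc")
)
stage_outputs <- list(
  train = c("model_pm25.json", "model_pm10.json"),
  predict = c("pm25_pred.asc", "pm10_pred.asc"),
  iaqi = c("ipm25.asc", "ipm10.asc"),
  paqi = "paqi.asc",
  exposure = "exposure.csv"
)

warn_stale <- function(out_dir, stages) {
  for (st in names(stage_outputs)) {
    if (st %in% stages) next # being regenerated anyway
    outs <- file.path(out_dir, stage_outputs[[st]])
    ins <- file.path(out_dir, stage_deps[[st]])
    if (all(file.exists(outs)) && any(file.exists(ins))) {
      ins <- ins[file.exists(ins)]
      if (max(file.mtime(ins)) > min(file.mtime(outs))) {
        warning("stale artifacts: outputs of stage '", st,
                "' are older than their inputs and the stage is not ",
                "being re-run", call. = FALSE)
      }
    }
  }
}
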