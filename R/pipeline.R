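#' Default pipeline configuration
#'
#' The thresholds of the method: the raw-intensity eligibility screen for
#' correlation scoring (intensity >= 0.01 in >= 3 fractions), the tight
#' co-elution cutoff (CC >= 0.85) and the target FDR (20%).
#'
#' @return A named list; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "coelute-run",
    model_kind = "ms_string",
    target_fdr = 0.20,
    lambda = 0.01,
    cc_eligibility_intensity = 0.01,
    cc_eligibility_fractions = 3,
    cc_threshold = 0.85,
    simulate = NULL,
    inputs = NULL
  )
}

.validate_pipeline_config <- function(config) {
  cfg <- modifyList(default_pipeline_config(), config)
  if (cfg$cc_threshold < -1 || cfg$cc_threshold > 1) {
    stop("cc_threshold must lie in [-1, 1]")
  }
  if (cfg$target_fdr < 0 || cfg$target_fdr > 1) {
    stop("target_fdr must lie in [0, 1]")
  }
  if (cfg$cc_eligibility_intensity < 0) {
    stop("cc_eligibility_intensity must be non-negative")
  }
  if (cfg$cc_eligibility_fractions < 1) {
    stop("cc_eligibility_fractions must be a positive count")
  }
  cfg$model_kind <- match.arg(cfg$model_kind, c("ms_string", "ms_only"))
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config must provide either 'simulate' parameters or 'inputs' paths")
  }
  if (!is.null(cfg$inputs)) {
    need <- c("abundance", "design", "annotation", "gold")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing) > 0) {
      stop("inputs is missing: ", paste(missing, collapse = ", "))
    }
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) stop("missing input file: ", p)
    }
  }
  cfg
}

.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the end-to-end prediction pipeline
#'
#' Stages: (1) obtain an elution dataset -- either simulated from
#' `config$simulate` parameters (see [simulation_config()]) or read from
#' `config$inputs` paths (`abundance`, `design`, `annotation`, `gold`, and
#' optionally `context`); (2) exclusion-filter and apex-normalize; (3)
#' assemble the eight-feature table; (4) score all co-occurring pairs under
#' one-operon-out cross-validation and threshold at the target FDR; (5)
#' write the feature table, prediction table and a JSON report. Outputs are
#' written atomically; rerunning with the same config reproduces identical
#' artifacts. Counts at every filtering step are logged via `message()`.
#'
#' @param config A named list or the path of a YAML file with the fields of
#'   [default_pipeline_config()].
#' @return Invisibly, a list with the dataset, feature table, predictions
#'   and the paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("seed: ", cfg$seed, "; model: ", cfg$model_kind,
          "; target FDR: ", cfg$target_fdr)

  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- simulate_experiment(do.call(simulation_config, sim_args))
    dataset <- sim$dataset
    gold <- sim$gold
    context <- sim$context
    write_simulation(sim, file.path(cfg$out_dir, "simulated-data"))
  } else {
    dataset <- read_elution_tables(cfg$inputs$abundance, cfg$inputs$design,
                                   cfg$inputs$annotation)
    gold_raw <- read_pair_list(cfg$inputs$gold)
    if (!"label" %in% names(gold_raw)) {
      stop("gold pair list needs a 'label' column (positive/negative)")
    }
    gold <- gold_standard(filter(gold_raw, .data$label == "positive"),
                          filter(gold_raw, .data$label == "negative"))
    context <- if (!is.null(cfg$inputs$context))
      read_context_table(cfg$inputs$context) else NULL
  }

  message("proteins detected: ", nrow(dataset$proteins))
  dataset <- filter_exclusions(dataset)
  message("after exclusion filtering: ", nrow(dataset$proteins))
  dataset <- normalize_apex(dataset)

  features <- assemble_features(
    dataset, context,
    cc_threshold = cfg$cc_threshold,
    min_intensity = cfg$cc_eligibility_intensity,
    min_fractions = cfg$cc_eligibility_fractions
  )
  message("co-occurring pairs: ", nrow(features))
  .write_atomic(function(p) write_feature_table(features, p),
                file.path(cfg$out_dir, "features.tsv"))

  operon_map <- select(dataset$proteins, "protein_id", "operon_id")
  gold_used <- semi_join(gold, features, by = c("protein_a", "protein_b"))
  message("gold pairs among candidates: ",
          sum(gold_used$label == "positive"), " positive, ",
          sum(gold_used$label == "negative"), " negative")

  scored <- cv_score_pairs(features, gold, operon_map,
                           model_kind = cfg$model_kind, lambda = cfg$lambda)
  predictions <- threshold_for_fdr(scored, target = cfg$target_fdr,
                                   model_kind = cfg$model_kind)
  message("predicted pairs at ", 100 * cfg$target_fdr, "% target FDR: ",
          nrow(predictions$predicted))
  .write_atomic(function(p) readr::write_tsv(tidy(predictions), p,
                                             progress = FALSE),
                file.path(cfg$out_dir, "predictions.tsv"))

  report <- as.list(glance(predictions))
  if (!is.null(sim)) {
    tm <- truth_metrics(predictions, sim$truth, candidates = features)
    report <- c(report, as.list(tm))
  }
  .write_atomic(function(p) jsonlite::write_json(report, p,
                                                 auto_unbox = TRUE,
                                                 digits = NA),
                file.path(cfg$out_dir, "report.json"))

  invisible(list(dataset = dataset, features = features,
                 predictions = predictions, simulation = sim,
                 report = report,
                 paths = file.path(cfg$out_dir,
                                   c("features.tsv", "predictions.tsv",
                                     "report.json"))))
}
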