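# Schema of the pipeline configuration: section -> key -> default.
# NULL defaults are "required when the command needs them".
config_schema <- function() {
  list(
    data = list(path = NULL, role_columns = NULL, yield_column = "yield_pct",
                id_column = NULL),
    features = list(radius = 2L, n_bits = 2048L,
                    mode = "numeric", numeric_prefix = "x_"),
    bias = list(yield_threshold_pct = 20, pu_ratio = 0.5, seed = 1L),
    pu = list(spy_rate = 0.1, spy_tolerance = 0.05, model_params = list()),
    cv = list(n_folds = 5L, validation_fraction = 0.10, hpo_trials = 0L,
              seed = 1L),
    synth = list(scenario = "separable", n_roles = 3L,
                 components_per_role = 13L, latent_dim = 6L,
                 separability = 4, target_positive_rate = 0.4,
                 yield_noise_sd = 2, n_records = 2000L, seed = 1L),
    sweep = list(grid_from = 0, grid_to = 1, grid_by = 0.02),
    output = list(dir = "payn_out")
  )
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file with nested sections (`data`,
#' `features`, `bias`, `pu`, `cv`, `synth`, `sweep`, `output`). Absent
#' keys take documented defaults; unknown sections or keys are errors
#' listing the valid ones; numeric values are range-checked against the
#' constraints of the module that owns them. Loading, serializing and
#' re-loading a configuration is idempotent.
#'
#' @param path YAML file path.
#' @return An object of class `pipeline_config`: the fully populated
#'   nested list, with the source text's FNV-1a hash in the
#'   `"config_hash"` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw, hash_src = paste(readLines(path, warn = FALSE),
                                           collapse = "\n"))
}

#' Build a pipeline configuration from a nested list
#'
#' Programmatic equivalent of [load_config()].
#'
#' @param raw nested named list mirroring the YAML layout (may be
#'   partial; defaults fill the rest).
#' @param hash_src optional character used for the provenance hash
#'   (defaults to the deparsed effective configuration).
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(raw = list(), hash_src = NULL) {
  schema <- config_schema()
  unknown_sec <- setdiff(names(raw), names(schema))
  if (length(unknown_sec))
    stopf("unknown config section '%s'; valid sections: %s",
          unknown_sec[1L], paste(names(schema), collapse = ", "))
  cfg <- schema
  for (sec in names(raw)) {
    entries <- raw[[sec]]
    unknown <- setdiff(names(entries), names(schema[[sec]]))
    if (length(unknown))
      stopf("unknown key '%s' in section '%s'; valid keys: %s",
            unknown[1L], sec, paste(names(schema[[sec]]), collapse = ", "))
    for (k in names(entries)) cfg[[sec]][[k]] <- entries[[k]]
  }
  validate_config(cfg)
  hash_src <- hash_src %||% paste(deparse(cfg), collapse = "\n")
  structure(cfg, class = "pipeline_config", config_hash = fnv1a32(hash_src))
}

validate_config <- function(cfg) {
  ck <- function(x, name, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stopf("config value %s = %s violates the constraint [%s, %s]",
            name, paste(x, collapse = ","), lo, hi)
  }
  ck(cfg$bias$pu_ratio, "bias.pu_ratio", 0, 1)
  ck(cfg$bias$yield_threshold_pct, "bias.yield_threshold_pct", -Inf, Inf)
  ck(cfg$pu$spy_rate, "pu.spy_rate", 1e-12, 1 - 1e-12)
  ck(cfg$pu$spy_tolerance, "pu.spy_tolerance", 0, 1 - 1e-12)
  ck(cfg$cv$n_folds, "cv.n_folds", 2, Inf)
  ck(cfg$cv$validation_fraction, "cv.validation_fraction", 1e-12, 1 - 1e-12)
  ck(cfg$cv$hpo_trials, "cv.hpo_trials", 0, Inf)
  ck(cfg$features$radius, "features.radius", 0, 5)
  ck(cfg$features$n_bits, "features.n_bits", 1, Inf)
  if (!cfg$features$mode %in% c("fingerprint", "passthrough", "numeric"))
    stopf("features.mode must be fingerprint, passthrough or numeric")
  ck(cfg$synth$target_positive_rate, "synth.target_positive_rate",
     1e-12, 1 - 1e-12)
  ck(cfg$synth$yield_noise_sd, "synth.yield_noise_sd", 0, Inf)
  invisible(cfg)
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path)
  invisible(path)
}

unclass_config <- function(config) {
  out <- unclass(config)
  attr(out, "config_hash") <- NULL
  # drop NULL-valued leaves so the YAML round trip is clean
  lapply(out, function(sec) Filter(Negate(is.null), sec))
}

config_featurizer <- function(cfg) {
  featurizer_spec(radius = cfg$features$radius, n_bits = cfg$features$n_bits,
                  mode = cfg$features$mode,
                  numeric_prefix = cfg$features$numeric_prefix)
}

config_synth_spec <- function(cfg, seed = NULL) {
  s <- cfg$synth
  if (!is.null(s$scenario) && nzchar(s$scenario %||% "")) {
    sp <- make_scenario(s$scenario, seed = seed %||% s$seed)
  } else {
    sp <- synthetic_spec(n_roles = s$n_roles,
                         components_per_role = s$components_per_role,
                         latent_dim = s$latent_dim,
                         separability = s$separability,
                         target_positive_rate = s$target_positive_rate,
                         yield_noise_sd = s$yield_noise_sd,
                         seed = seed %||% s$seed,
                         n_records = s$n_records)
  }
  sp
}

log_info <- function(verbose, fmt, ...) {
  message(sprintf(paste0("[payn] ", fmt), ...))
  invisible(NULL)
}

# Load the input table and its features as the config prescribes.
config_load_data <- function(cfg) {
  if (is.null(cfg$data$path)) stopf("config is missing data.path")
  if (is.null(cfg$data$role_columns)) stopf("config is missing data.role_columns")
  tab <- read_reaction_table(cfg$data$path,
                             role_columns = unlist(cfg$data$role_columns),
                             yield_column = cfg$data$yield_column,
                             id_column = cfg$data$id_column)
  feats <- featurize_reaction(tab, config_featurizer(cfg))
  list(table = tab, features = feats)
}

#' Run a pipeline command
#'
#' Library-level orchestration behind the command-line interface; the
#' CLI is a thin shell over this function and produces identical
#' results.
#'
#' \describe{
#'   \item{`"synth"`}{write a synthetic reaction CSV
#'     (`synthetic.csv`).}
#'   \item{`"pu-extract"`}{bias-simulate, run the spy pipeline, and
#'     write `reliable_negatives.csv` plus `metrics.json`.}
#'   \item{`"sweep"`}{as above, then sweep the RN threshold over a grid
#'     and write `sweep.csv`.}
#'   \item{`"benchmark"`}{run the three-model cross-validated benchmark
#'     and write `benchmark.json`.}
#' }
#'
#' @param command one of `"synth"`, `"pu-extract"`, `"sweep"`,
#'   `"benchmark"`.
#' @param config a `pipeline_config`.
#' @param out_dir output directory override (default
#'   `config$output$dir`).
#' @param seed optional global seed override; per-stage seeds are
#'   derived from it deterministically.
#' @param verbose emit per-stage log lines.
#' @return Character vector of written artifact paths, invisibly.
#' @export
payn_run <- function(command = c("synth", "pu-extract", "sweep", "benchmark"),
                     config, out_dir = NULL, seed = NULL, verbose = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$output$dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- attr(config, "config_hash")
  provenance <- list(config_hash = hash,
                     seed = seed %||% config$bias$seed,
                     command = command)
  if (verbose) log_info(verbose, "command=%s config=%s", command, hash)

  if (command == "synth") {
    sp <- config_synth_spec(config, seed = seed)
    gen <- generate_hte_dataset(sp)
    path <- file.path(out_dir, "synthetic.csv")
    write_synthetic_csv(gen, path)
    if (verbose) log_info(verbose, "synth: %d records -> %s", nrow(gen$table), path)
    return(invisible(path))
  }

  dat <- config_load_data(config)
  bias <- bias_spec(config$bias$yield_threshold_pct, config$bias$pu_ratio,
                    seed %||% config$bias$seed)

  if (command %in% c("pu-extract", "sweep")) {
    labels <- binarize_yields(dat$table, bias$yield_threshold_pct)
    if (sum(labels$y) == 0L)
      stopf("no reaction exceeds the yield threshold of %s%%: nothing to learn from",
            bias$yield_threshold_pct)
    pu <- make_pu_dataset(dat$table, labels, bias)
    assignment <- inject_spies(pu, spy_rate = config$pu$spy_rate,
                               seed = derive_seed(bias$seed, "spies"))
    clf <- fit_pu_classifier(dat$features, assignment, config$pu$model_params)
    thr <- compute_spy_threshold(
      predict(clf, dat$features, ids = assignment$spy_ids),
      config$pu$spy_tolerance)
    rn <- extract_reliable_negatives(pu, assignment, clf, dat$features, thr)
    if (verbose)
      log_info(verbose, "%d RN of %d unlabeled at t_spies=%.4f",
               length(rn$rn_ids), length(pu$unlabeled), thr$t_spies)
    if (command == "pu-extract") {
      report <- rn_confusion_metrics(rn, pu)
      paths <- write_outputs(rn, report, out_dir, provenance = provenance)
      return(invisible(paths))
    }
    grid <- seq(config$sweep$grid_from, config$sweep$grid_to,
                by = config$sweep$grid_by)
    sw <- threshold_sweep(rn$scores, pu, grid)
    path <- file.path(out_dir, "sweep.csv")
    utils::write.csv(as.data.frame(sw), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }

  # benchmark
  cvs <- cv_spec(n_folds = config$cv$n_folds,
                 validation_fraction = config$cv$validation_fraction,
                 seed = seed %||% config$cv$seed,
                 hpo_trials = config$cv$hpo_trials)
  report <- run_benchmark_cv(dat$table, dat$features, bias = bias,
                             spy_rate = config$pu$spy_rate,
                             tolerance = config$pu$spy_tolerance,
                             cv = cvs, model_params = config$pu$model_params)
  path <- file.path(out_dir, "benchmark.json")
  write_benchmark_json(report, path, provenance = provenance)
  if (verbose)
    log_info(verbose, "benchmark: gap closed %.1f%% -> %s",
             report$gap_closed_pct, path)
  invisible(path)
}
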