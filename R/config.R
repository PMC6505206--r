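## Run configuration: a single key-value file (YAML or JSON) holding the
## rate constants, signal program, solver settings and analysis block, with
## strict validation so placeholder values never slip through silently.

config_template <- function() {
  list(
    model_id = "model1",
    provenance = "packaged_default",
    rates = default_rates(),
    signals = unclass(signal_program()),
    solver = list(rtol = 1e-8, atol = 1e-10, grid = 0.05),
    analysis = list(intensity = 0.10, n = 5000, seed = 1,
                    intensities = c(0.05, 0.10, 0.15, 0.20, 0.25),
                    n_iter = 10000, t_end = 30),
    outdir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration, fills
#' missing optional blocks with the packaged defaults, and validates:
#' unknown keys are rejected, rates must be nonnegative, `model_id` must
#' name one of the three systems, and the `provenance` field is mandatory
#' so results are never silently computed against placeholder rates.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config` list.
#' @seealso [save_config()], [default_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  tpl <- config_template()
  unknown <- setdiff(names(cfg), names(tpl))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$provenance))
    stop("configuration must state 'provenance' (one of packaged_default, ",
         "table_s1, table_s2)", call. = FALSE)
  if (!cfg$provenance %in% c("packaged_default", "table_s1", "table_s2"))
    stop("invalid provenance: ", cfg$provenance, call. = FALSE)
  if (!is.null(cfg$model_id) &&
      !cfg$model_id %in% c("model1", "model2", "combined"))
    stop("unknown model_id: ", cfg$model_id, call. = FALSE)
  for (blk in c("rates", "signals", "solver", "analysis")) {
    if (is.null(cfg[[blk]])) { cfg[[blk]] <- tpl[[blk]]; next }
    bad <- setdiff(names(cfg[[blk]]), names(tpl[[blk]]))
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[[blk]] <- utils::modifyList(tpl[[blk]], as.list(cfg[[blk]]))
  }
  for (nm in names(cfg$rates))
    if (!is.numeric(cfg$rates[[nm]]) || cfg$rates[[nm]] < 0)
      stop("rate constant '", nm, "' must be nonnegative", call. = FALSE)
  if (is.null(cfg$model_id)) cfg$model_id <- tpl$model_id
  if (is.null(cfg$outdir)) cfg$outdir <- tpl$outdir
  cfg <- cfg[names(tpl)]
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes YAML or JSON depending on the file extension. `load_config()` of
#' the saved file round-trips to an equal configuration.
#'
#' @param cfg A `run_config` (or plain list in the same shape).
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(unclass(cfg))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' The packaged default configuration
#'
#' @return A validated `run_config` with the calibrated default rates, the
#'   published signal program (GF = 1, F_T = 5) and default analysis
#'   settings.
#' @export
default_config <- function() {
  validate_config(config_template())
}

#' Materialize configured objects
#'
#' Convenience accessors turning a `run_config` into the package's domain
#' objects.
#'
#' @param cfg A `run_config`.
#' @return [config_params()] a [rate_parameters()]; [config_prog()] a
#'   [signal_program()].
#' @export
config_params <- function(cfg) {
  do.call(rate_parameters, c(cfg$rates, list(provenance = cfg$provenance)))
}

#' @rdname config_params
#' @export
config_prog <- function(cfg) {
  do.call(signal_program, cfg$signals)
}

#' Generate the deterministic fixtures used by the test suite
#'
#' Writes a small seeded parameter ensemble (n = 50, Model 2), a switch
#' sample list (n = 100) and a reference Model 1 trajectory, each with a
#' JSON manifest. Byte-identical across invocations with the same seed.
#'
#' @param outdir Writable output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  ens <- sample_parameters(param_names = ensemble_param_names("model2"),
                           intensity = 0.10, n = 50, seed = seed,
                           model_id = "model2")
  ens <- run_ensemble(ens)
  p <- file.path(outdir, "ensemble_model2_n50.csv")
  write_ensemble(ens, p); paths <- c(paths, p, paste0(p, ".json"))
  sws <- sample_switch_structures(100, T_end = 30, seed = seed)
  sw_df <- data.frame(t_on = vapply(sws, `[[`, numeric(1), "t_on"),
                      duration = vapply(sws, `[[`, numeric(1), "duration"))
  p <- file.path(outdir, "switch_samples_n100.csv")
  utils::write.csv(sw_df, p, row.names = FALSE); paths <- c(paths, p)
  traj <- simulate_model1(grid = 0.1)
  p <- file.path(outdir, "trajectory_model1.csv")
  write_trajectory(traj, p); paths <- c(paths, p)
  jsonlite::write_json(list(seed = seed, package = "mycdeg",
                            files = basename(paths)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(outdir, "manifest.json")))
}
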