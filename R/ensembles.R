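## Perturbation ensembles: the stochastic inputs of the sensitivity and
## robustness analyses, and the uniform switch-structure samples of the
## decision-process search.

## Which sampled names map where. "erk", "gsk" and "gf" perturb the pulse
## amplitude E_Max, G_Max and the growth-factor level GF; the remaining
## signal names perturb the corresponding program fields (robustness only).
SIGNAL_PARAM_MAP <- c(erk = "E_Max", gsk = "G_Max", gf = "GF",
                      Dur_E = "Dur_E", Dur_G1 = "Dur_G1",
                      Dur_G2 = "Dur_G2", Width_G = "Width_G")

#' Parameter names sampled for each model
#'
#' The sensitivity analysis perturbs the rate constants of the model plus
#' the signal amplitudes (`erk`, `gsk`, `gf` for Model 1; Model 2 has no
#' pulsed inputs). Robustness ensembles (`robustness = TRUE`) additionally
#' perturb the durations and width of the Erk and GSK3beta pulses.
#'
#' @param model_id `"model1"`, `"model2"` or `"combined"`.
#' @param robustness Include the pulse duration/width fields?
#' @return Character vector of parameter names.
#' @export
ensemble_param_names <- function(model_id = c("model1", "model2", "combined"),
                                 robustness = FALSE) {
  model_id <- match.arg(model_id)
  base <- switch(model_id,
    model1 = c(paste0("k", 1:11), "erk", "gsk", "gf"),
    model2 = c("k1", "k2", "k11", "k12", "k13", "k14"),
    combined = c(paste0("k", 1:14), "erk", "gsk", "gf"))
  if (robustness && model_id != "model2")
    base <- c(base, "Dur_E", "Dur_G1", "Dur_G2", "Width_G")
  base
}

nominal_values <- function(param_names, params, prog) {
  vapply(param_names, function(nm) {
    if (nm %in% names(SIGNAL_PARAM_MAP)) prog[[SIGNAL_PARAM_MAP[[nm]]]]
    else if (nm %in% paste0("k", 1:14)) unname(as.numeric(params)[match(nm, paste0("k", 1:14))])
    else stop("unknown parameter name: ", nm, call. = FALSE)
  }, numeric(1))
}

#' Draw a Gaussian parameter-perturbation ensemble
#'
#' Each selected parameter is drawn i.i.d. from a normal distribution
#' centred on its nominal value with standard deviation
#' `intensity * nominal` (the perturbation intensity is a coefficient of
#' variation). Non-positive draws are rejected and redrawn, preserving the
#' distribution shape near the mode rather than piling mass at a clip
#' boundary.
#'
#' @param params Nominal [rate_parameters()].
#' @param prog Nominal [signal_program()].
#' @param param_names Names to perturb; see [ensemble_param_names()].
#' @param intensity Fractional perturbation strength (e.g. 0.10 for 10%).
#' @param n Number of samples (rows).
#' @param seed Integer seed; the ensemble is reproducible bit-for-bit.
#' @param model_id Which system the ensemble is destined for.
#' @return An object of class `myc_ensemble`: list with the sample matrix
#'   (`n` x `p`), nominals, intensity, seed and (until run) empty outputs.
#' @examples
#' ens <- sample_parameters(n = 10, intensity = 0.1, seed = 1)
#' colMeans(ens$samples)
#' @export
sample_parameters <- function(params = rate_parameters(),
                              prog = signal_program(),
                              param_names = ensemble_param_names("model1"),
                              intensity = 0.10, n = 5000, seed = 1,
                              model_id = c("model1", "model2", "combined")) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(params, "rate_parameters"), inherits(prog, "signal_program"))
  if (!is.numeric(intensity) || intensity < 0)
    stop("intensity must be >= 0", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("n must be at least 2", call. = FALSE)
  known <- c(paste0("k", 1:14), names(SIGNAL_PARAM_MAP))
  bad <- setdiff(param_names, known)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nom <- nominal_values(param_names, params, prog)
  if (intensity > 0 && any(nom <= 0))
    stop("cannot perturb parameter(s) with non-positive nominal value: ",
         paste(param_names[nom <= 0], collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  X <- vapply(nom, function(v) {
    d <- stats::rnorm(n, v, intensity * v)
    while (any(d <= 0) && intensity > 0)
      d[d <= 0] <- stats::rnorm(sum(d <= 0), v, intensity * v)
    d
  }, numeric(n))
  if (intensity == 0) X <- matrix(rep(nom, each = n), nrow = n,
                                  dimnames = list(NULL, param_names))
  colnames(X) <- param_names
  structure(list(samples = X, nominal = nom, intensity = intensity,
                 n = as.integer(n), seed = as.integer(seed),
                 model_id = model_id, params = params, prog = prog,
                 outputs = NULL, status = NULL),
            class = "myc_ensemble")
}

#' @export
print.myc_ensemble <- function(x, ...) {
  cat(sprintf("<myc_ensemble> %s: %d samples x %d parameters, intensity %.0f%%, seed %d\n",
              x$model_id, x$n, ncol(x$samples), 100 * x$intensity, x$seed))
  if (!is.null(x$outputs))
    cat(sprintf("  outputs: %d ok, %d failed\n",
                sum(x$status == "ok"), sum(x$status != "ok")))
  invisible(x)
}

#' Draw uniform switch structures
#'
#' Switch-on time and duration drawn independently from U(0, T_end); the
#' effective on-window is clipped at the horizon.
#'
#' @param n Number of structures.
#' @param T_end Horizon (h).
#' @param seed Integer seed.
#' @return List of [switch_structure()] objects.
#' @export
sample_switch_structures <- function(n, T_end = 30, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  t_on <- stats::runif(n, 0, T_end)
  dur <- stats::runif(n, 0, T_end)
  lapply(seq_len(n), function(i)
    switch_structure(t_on = t_on[i], duration = dur[i], T_end = T_end))
}

apply_sample <- function(row, params, prog) {
  k <- as.numeric(params)
  names(k) <- paste0("k", 1:14)
  pr <- unclass(prog)
  for (nm in names(row)) {
    if (nm %in% names(SIGNAL_PARAM_MAP)) pr[[SIGNAL_PARAM_MAP[[nm]]]] <- row[[nm]]
    else k[[nm]] <- row[[nm]]
  }
  ## perturbed durations can invert; keep the program valid by ordering
  if (pr$Dur_G1 >= pr$Dur_G2) pr$Dur_G2 <- pr$Dur_G1 + 1e-6
  list(params = do.call(rate_parameters,
                        c(as.list(k), provenance = attr(params, "provenance"))),
       prog = do.call(signal_program, pr))
}

#' Simulate every sample of an ensemble
#'
#' Runs the model once per row of the sample matrix and stores the model
#' output (the ubiquitinated fraction at the horizon). Individual solver
#' failures are recorded per row; more than 1% failures aborts with an
#' ensemble-quality error.
#'
#' @param ensemble A `myc_ensemble` from [sample_parameters()].
#' @param t_end Horizon (h).
#' @param sw Switch structure for the combined model (optional).
#' @return The ensemble with `outputs` and `status` filled.
#' @export
run_ensemble <- function(ensemble, t_end = 30, sw = NULL) {
  stopifnot(inherits(ensemble, "myc_ensemble"))
  X <- ensemble$samples
  out <- numeric(nrow(X))
  status <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    cfg <- apply_sample(as.list(X[i, , drop = TRUE]),
                        ensemble$params, ensemble$prog)
    res <- tryCatch({
      traj <- switch(ensemble$model_id,
        model1 = simulate_model1(cfg$params, cfg$prog, t_end = t_end,
                                 grid = t_end),
        model2 = simulate_model2(cfg$params, cfg$prog, t_end = t_end,
                                 grid = t_end),
        combined = simulate_combined(cfg$params, cfg$prog, sw = sw,
                                     t_end = t_end, grid = t_end))
      model_output(traj)
    }, error = function(e) NA_real_)
    out[i] <- res
    status[i] <- if (is.finite(res)) "ok" else "failed"
  }
  if (mean(status != "ok") > 0.01)
    stop("run_ensemble: more than 1% of the ", nrow(X),
         " integrations failed", call. = FALSE)
  ensemble$outputs <- out
  ensemble$status <- status
  ensemble
}

#' Write an ensemble to CSV with a JSON manifest
#'
#' One row per sample (parameters, output, status) plus `<path>.json`
#' recording seed, intensity and model.
#'
#' @param ensemble A run `myc_ensemble`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "myc_ensemble"))
  df <- as.data.frame(ensemble$samples)
  df$output <- if (is.null(ensemble$outputs)) NA_real_ else ensemble$outputs
  df$status <- if (is.null(ensemble$status)) NA_character_ else ensemble$status
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(model_id = ensemble$model_id, n = ensemble$n,
                   intensity = ensemble$intensity, seed = ensemble$seed,
                   nominal = as.list(ensemble$nominal))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
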