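## Robustness: dispersion of the model output under increasing Gaussian
## perturbation of the rate constants and signal inputs, summarized by the
## moving average of the output against the total normalized parameter
## variation.

#' Total normalized parameter variation
#'
#' The summed normalized absolute deviation of a sampled parameter set
#' from nominal, `sum_i |p_i - p_i0| / p_i0` — the x-axis of the
#' robustness analysis.
#'
#' @param sample Named numeric vector (one ensemble row).
#' @param nominal Named numeric vector of positive nominal values.
#' @return Nonnegative scalar; 0 only for the unperturbed sample.
#' @examples
#' total_parameter_variation(c(a = 2, b = 1), c(a = 1, b = 1))  # 1
#' @export
total_parameter_variation <- function(sample, nominal) {
  if (is.null(names(sample)) || is.null(names(nominal)) ||
      !setequal(names(sample), names(nominal)))
    stop("sample and nominal must carry matching names", call. = FALSE)
  nominal <- nominal[names(sample)]
  if (any(nominal <= 0))
    stop("nominal values must be positive", call. = FALSE)
  sum(abs(sample - nominal) / nominal)
}

#' Moving average of one series over the sorted order of another
#'
#' `ys` is averaged in a sliding window of `window` consecutive points
#' taken in increasing order of `xs`; used to smooth the output scatter
#' against total parameter variation. `window = 1` returns `ys` in sorted
#' order unchanged.
#'
#' @param xs Numeric vector (the sorting variable).
#' @param ys Numeric vector, same length.
#' @param window Window size in points.
#' @return Data frame with columns `x` (window-mean of `xs`) and `y`
#'   (window-mean of `ys`), `length(xs) - window + 1` rows.
#' @examples
#' moving_average(1:4, c(1, 2, 3, 4), window = 2)$y  # 1.5 2.5 3.5
#' @export
moving_average <- function(xs, ys, window) {
  if (length(xs) != length(ys))
    stop("xs and ys must have equal length", call. = FALSE)
  if (!is.numeric(window) || window < 1 || window != round(window))
    stop("window must be a positive integer", call. = FALSE)
  if (window > length(xs))
    stop("window exceeds the series length", call. = FALSE)
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  cx <- cumsum(c(0, xs)); cy <- cumsum(c(0, ys))
  i <- seq_len(length(xs) - window + 1L)
  data.frame(x = (cx[i + window] - cx[i]) / window,
             y = (cy[i + window] - cy[i]) / window)
}

#' Perturbation-ensemble robustness analysis
#'
#' For each perturbation intensity: draws a Gaussian ensemble (rate
#' constants plus, for Model 1 and the combined model, the signal
#' amplitudes, durations and width), simulates it, computes each sample's
#' total parameter variation and output, the moving-average curve of
#' output against total variation, and a fluctuation score — the standard
#' deviation of the moving-average curve, which operationalizes "low
#' variation in the moving average" as a single number per intensity.
#'
#' @param model_id `"model1"` or `"model2"` (or `"combined"`).
#' @param params Nominal [rate_parameters()].
#' @param prog Nominal [signal_program()].
#' @param intensities Ascending fractional intensities.
#' @param n Ensemble size per intensity.
#' @param seed Integer seed (one independent substream per intensity).
#' @param t_end Horizon (h).
#' @param window Moving-average window (points); default `n / 50`.
#' @return An object of class `robustness_result`: per-intensity list with
#'   total variation, outputs, moving-average curve and fluctuation score,
#'   plus a `summary` data frame.
#' @export
run_robustness <- function(model_id = c("model1", "model2", "combined"),
                           params = rate_parameters(),
                           prog = signal_program(),
                           intensities = c(0.05, 0.10, 0.15, 0.20, 0.25),
                           n = 5000, seed = 1, t_end = 30, window = NULL) {
  model_id <- match.arg(model_id)
  if (is.unsorted(intensities) || any(intensities < 0))
    stop("intensities must be ascending and nonnegative", call. = FALSE)
  if (is.null(window)) window <- max(1L, as.integer(round(n / 50)))
  nm <- ensemble_param_names(model_id, robustness = TRUE)
  per <- vector("list", length(intensities))
  names(per) <- paste0("intensity_", intensities)
  for (i in seq_along(intensities)) {
    ens <- sample_parameters(params, prog, nm, intensities[i], n,
                             seed = seed + i - 1L, model_id = model_id)
    ens <- run_ensemble(ens, t_end = t_end)
    ok <- ens$status == "ok"
    tv <- apply(ens$samples[ok, , drop = FALSE], 1,
                total_parameter_variation, nominal = ens$nominal)
    ma <- moving_average(tv, ens$outputs[ok], min(window, sum(ok)))
    per[[i]] <- list(intensity = intensities[i], total_variation = unname(tv),
                     outputs = ens$outputs[ok], moving_average = ma,
                     fluctuation = stats::sd(ma$y))
  }
  fl <- vapply(per, `[[`, numeric(1), "fluctuation")
  fl[intensities == 0] <- 0   # sd of a constant curve; guard length-1 NA
  summary <- data.frame(intensity = intensities, fluctuation = unname(fl))
  structure(list(model_id = model_id, per_intensity = per, summary = summary,
                 n = n, seed = seed, window = window),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> %s: n = %d per intensity\n",
              x$model_id, x$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare the robustness of two models
#'
#' Per-intensity comparison of fluctuation scores on the shared intensity
#' grid plus a summary verdict: the model with the lower mean fluctuation
#' is the more robust. Swapping the arguments flips the verdict.
#'
#' @param r1,r2 `robustness_result` objects.
#' @return List with the per-intensity table and `verdict` (one of
#'   `"first more robust"`, `"second more robust"`, `"tie"`).
#' @export
compare_robustness <- function(r1, r2) {
  stopifnot(inherits(r1, "robustness_result"), inherits(r2, "robustness_result"))
  shared <- intersect(r1$summary$intensity, r2$summary$intensity)
  if (!length(shared))
    stop("compare_robustness: disjoint intensity grids", call. = FALSE)
  f1 <- r1$summary$fluctuation[match(shared, r1$summary$intensity)]
  f2 <- r2$summary$fluctuation[match(shared, r2$summary$intensity)]
  tab <- data.frame(intensity = shared, fluctuation_1 = f1, fluctuation_2 = f2,
                    more_robust = ifelse(f1 < f2, r1$model_id,
                                  ifelse(f2 < f1, r2$model_id, "tie")))
  m1 <- mean(f1); m2 <- mean(f2)
  verdict <- if (isTRUE(all.equal(m1, m2)) || m1 == m2) "tie"
             else if (m1 < m2) "first more robust" else "second more robust"
  list(table = tab, verdict = verdict,
       mean_fluctuation = c(m1, m2))
}

#' Write robustness scatter and moving-average data to CSV
#'
#' Writes `<path>` with pooled per-sample rows (intensity, total_variation,
#' output) and `<path>` with suffix `_ma.csv` holding the per-intensity
#' moving-average curves; a JSON summary sits alongside.
#'
#' @param result A `robustness_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_robustness <- function(result, path) {
  stopifnot(inherits(result, "robustness_result"))
  scatter <- do.call(rbind, lapply(result$per_intensity, function(p)
    data.frame(intensity = p$intensity, total_variation = p$total_variation,
               output = p$outputs)))
  utils::write.csv(scatter, path, row.names = FALSE)
  ma <- do.call(rbind, lapply(result$per_intensity, function(p)
    data.frame(intensity = p$intensity, p$moving_average)))
  utils::write.csv(ma, sub("\\.csv$", "_ma.csv", path), row.names = FALSE)
  jsonlite::write_json(list(model_id = result$model_id, n = result$n,
                            seed = result$seed,
                            summary = result$summary),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
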