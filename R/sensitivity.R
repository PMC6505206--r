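## Correlation-coefficient parameter sensitivity: Pearson (CC), Spearman
## rank (RCC) and partial rank (PRCC) correlations between each sampled
## parameter and the model output, with two-sided t-tests.

check_cor_input <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("x and y must be numeric vectors of equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  invisible(TRUE)
}

#' Pearson correlation coefficient (CC)
#'
#' Standard product-moment correlation. Zero-variance inputs raise an
#' error rather than returning NA, so a misconfigured ensemble fails
#' loudly.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation coefficient (RCC)
#'
#' Pearson correlation of the average-ranked data (ties receive their mean
#' rank).
#'
#' @inheritParams pearson_cc
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rcc <- function(x, y) {
  check_cor_input(x, y)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate input: zero rank variance", call. = FALSE)
  stats::cor(rx, ry, method = "pearson")
}

#' Partial rank correlation coefficients (PRCC)
#'
#' For each parameter column j: rank-transform all columns and the output,
#' regress both ranked j and the ranked output on all the other ranked
#' parameters (with intercept), and return the Pearson correlation of the
#' two residual vectors. This isolates the monotone association of each
#' parameter with the output after removing the (linear-in-ranks) effects
#' of the remaining parameters.
#'
#' @param sample_matrix Numeric matrix, n samples x p parameters.
#' @param outputs Numeric vector of length n.
#' @return Named vector of p partial rank correlations.
#' @export
prcc <- function(sample_matrix, outputs) {
  X <- as.matrix(sample_matrix)
  if (!is.numeric(X) || !is.numeric(outputs) || nrow(X) != length(outputs))
    stop("sample_matrix rows must match outputs length", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2)
    stop("need n > p + 2 samples for PRCC", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: constant column(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  R <- apply(X, 2, rank)
  ry <- rank(outputs)
  out <- numeric(p)
  for (j in seq_len(p)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop("rank-deficient design: collinear column(s) among ",
           paste(colnames(X)[-j], collapse = ", "), call. = FALSE)
    res_j <- qr.resid(qz, R[, j])
    res_y <- qr.resid(qz, ry)
    if (stats::sd(res_j) == 0 || stats::sd(res_y) == 0)
      stop("degenerate residuals for column ", colnames(X)[j], call. = FALSE)
    out[j] <- stats::cor(res_j, res_y)
  }
  stats::setNames(out, colnames(X))
}

#' Two-sided t-test for a correlation coefficient
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t-distribution with
#' `n - 2` degrees of freedom; p tends to 0 as |r| tends to 1.
#'
#' @param r Correlation in `[-1, 1]`.
#' @param n Sample size (>= 4).
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' correlation_t_test(0.5, 12)  # ~0.098
#' @export
correlation_t_test <- function(r, n) {
  if (!is.numeric(r) || any(abs(r) > 1))
    stop("r must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(n) || any(n < 4))
    stop("n must be at least 4", call. = FALSE)
  ifelse(abs(r) == 1, 0, {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  })
}

#' Correlation-based parameter sensitivity analysis
#'
#' Draws a Gaussian perturbation ensemble about the nominal parameters,
#' simulates every sample, and computes CC, RCC and PRCC of each parameter
#' against the model output (gamma at the horizon for Model 1 and the
#' combined model, gamma' for Model 2), with two-sided t-test p-values.
#'
#' @param model_id `"model1"`, `"model2"` or `"combined"`.
#' @param params Nominal [rate_parameters()].
#' @param prog Nominal [signal_program()].
#' @param intensity Perturbation intensity (coefficient of variation).
#' @param n Ensemble size.
#' @param seed Integer seed.
#' @param t_end Horizon (h).
#' @return An object of class `sensitivity_result`: a data frame with one
#'   row per parameter and columns `parameter`, `CC`, `RCC`, `PRCC`,
#'   `p_CC`, `p_RCC`, `p_PRCC`, plus metadata attributes (and the ensemble
#'   as attribute `ensemble`).
#' @examples
#' \donttest{
#' res <- run_sensitivity("model2", n = 200, seed = 1)
#' res[order(-abs(res$CC)), ]
#' }
#' @export
run_sensitivity <- function(model_id = c("model1", "model2", "combined"),
                            params = rate_parameters(),
                            prog = signal_program(),
                            intensity = 0.10, n = 5000, seed = 1,
                            t_end = 30) {
  model_id <- match.arg(model_id)
  nm <- ensemble_param_names(model_id, robustness = FALSE)
  ens <- sample_parameters(params, prog, nm, intensity, n, seed, model_id)
  ens <- run_ensemble(ens, t_end = t_end)
  ok <- ens$status == "ok"
  X <- ens$samples[ok, , drop = FALSE]
  y <- ens$outputs[ok]
  cc <- apply(X, 2, pearson_cc, y = y)
  rcc <- apply(X, 2, spearman_rcc, y = y)
  pr <- prcc(X, y)
  nn <- sum(ok)
  df <- data.frame(parameter = nm,
                   CC = unname(cc), RCC = unname(rcc), PRCC = unname(pr),
                   p_CC = correlation_t_test(unname(cc), nn),
                   p_RCC = correlation_t_test(unname(rcc), nn),
                   p_PRCC = correlation_t_test(unname(pr), nn),
                   row.names = NULL)
  structure(df, class = c("sensitivity_result", "data.frame"),
            model_id = model_id, n = nn, intensity = intensity, seed = seed,
            ensemble = ens)
}

#' @export
print.sensitivity_result <- function(x, digits = 3, ...) {
  cat(sprintf("<sensitivity_result> %s: n = %d, intensity = %.0f%%\n",
              attr(x, "model_id"), attr(x, "n"), 100 * attr(x, "intensity")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity table (and optional scatter data) to CSV
#'
#' The main CSV mirrors the published tables (parameter, CC, RCC, PRCC and
#' p-values). With `scatter = TRUE` a companion long-format CSV
#' `<path>_scatter.csv` holds (parameter, value, output) per sample for
#' scatter plots.
#'
#' @param result A `sensitivity_result`.
#' @param path CSV output path.
#' @param scatter Also write the per-sample long-format data?
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(result, path, scatter = FALSE) {
  stopifnot(inherits(result, "sensitivity_result"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  if (scatter) {
    ens <- attr(result, "ensemble")
    long <- do.call(rbind, lapply(colnames(ens$samples), function(nm)
      data.frame(parameter = nm, value = ens$samples[, nm],
                 output = ens$outputs)))
    utils::write.csv(long, sub("\\.csv$", "_scatter.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
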