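#' Ubiquitinated fraction of c-Myc
#'
#' The dimensionless model output: `x4 / (x1 + x2 + x3 + x4)` over the four
#' c-Myc pools (`mode = "four_pool"`, gamma, Models 1 and combined) or
#' `x4 / (x1 + x4)` over the two pools of Model 2 (`mode = "two_pool"`,
#' gamma'). Defined as 0 when the total is 0, which with the default zero
#' initial conditions occurs only at t = 0.
#'
#' @param state Named nonnegative state vector containing `x4` and the
#'   other pools required by `mode` (`x1`, `x2`, `x3` or just `x1`).
#' @param mode `"four_pool"` or `"two_pool"`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' gamma_fraction(c(x1 = 1, x2 = 1, x3 = 1, x4 = 1))  # 0.25
#' gamma_fraction(c(x1 = 1, x4 = 1), mode = "two_pool")  # 0.5
#' @export
gamma_fraction <- function(state, mode = c("four_pool", "two_pool")) {
  mode <- match.arg(mode)
  need <- if (mode == "four_pool") c("x1", "x2", "x3", "x4") else c("x1", "x4")
  if (!all(need %in% names(state)))
    stop("gamma_fraction: state must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(state[need])
  if (any(!is.finite(v)) || any(v < 0))
    stop("gamma_fraction: pools must be finite and nonnegative", call. = FALSE)
  tot <- sum(v)
  if (tot == 0) return(0)
  v[length(v)] / tot
}

#' Model output: ubiquitinated fraction at the end of the time course
#'
#' The scalar used by the sensitivity and robustness analyses: gamma (or
#' gamma') evaluated at the final time point of the trajectory. The system
#' is driven by time-varying pulses, so "steady state" is operationalized
#' as the state at the solve horizon (30 h by default).
#'
#' @param traj A `myc_trajectory`.
#' @return gamma (four-pool) or gamma' (two-pool) at the last time point.
#' @export
model_output <- function(traj) {
  stopifnot(inherits(traj, "myc_trajectory"))
  if (nrow(traj) < 2L)
    stop("model_output: trajectory is truncated", call. = FALSE)
  traj$gamma[nrow(traj)]
}

#' Accumulated ubiquitinated c-Myc J
#'
#' The optimization objective of the switch search: the time integral of
#' the ubiquitinated pool, `J = int_0^T x4(t) dt` (concentration x hours),
#' evaluated by the trapezoidal rule on the stored time grid.
#'
#' @param traj A `myc_trajectory`.
#' @return Nonnegative scalar.
#' @examples
#' objective_J(simulate_combined(sw = switch_structure(0, 30)))
#' @export
objective_J <- function(traj) {
  stopifnot(inherits(traj, "myc_trajectory"))
  if (nrow(traj) < 2L)
    stop("objective_J: trajectory grid is too short", call. = FALSE)
  t <- traj$time; x4 <- traj$x4
  sum(diff(t) * (x4[-length(x4)] + x4[-1]) / 2)
}
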