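#' @useDynLib mycdeg, .registration = TRUE
#' @importFrom deSolve lsoda
NULL

## Piecewise integration driver.
##
## The pulsed inputs make the right-hand side discontinuous in t, which
## adaptive steppers handle badly if allowed to step across a jump. The
## driver therefore splits [0, t_end] at every signal breakpoint, holds the
## signal levels constant inside each segment (they are piecewise constant
## by construction), and chains lsoda calls, restarting from the previous
## segment's final state.
##
## `times` is the requested output grid; segment boundaries are always
## included in the solve so no accuracy is lost at the joints.
integrate_piecewise <- function(y0, times, breaks, func, init, parms_for,
                                rtol, atol) {
  ## `times` is sorted, unique, starts at 0 and contains every breakpoint.
  breaks <- sort(unique(c(0, breaks, max(times))))
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0) + 1L)
  out[, 1L] <- times
  out[1L, -1L] <- y0
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    if (b - a <= 0) next
    sel <- which(times > a & times <= b)   # output points owed by this segment
    tt <- c(a, times[sel])
    sol <- tryCatch(
      deSolve::lsoda(y = y, times = tt, func = func, parms = parms_for(a),
                     dllname = "mycdeg", initfunc = init,
                     rtol = rtol, atol = atol),
      warning = function(w) stop("integration failed near t = ", a, ": ",
                                 conditionMessage(w), call. = FALSE)
    )
    if (nrow(sol) < length(tt))
      stop("integration failed near t = ", sol[nrow(sol), 1L], call. = FALSE)
    out[sel, -1L] <- sol[-1L, -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }
  out
}

make_time_grid <- function(t_end, grid, breaks) {
  if (is.null(grid)) grid <- 0.05
  if (!is.numeric(grid) || length(grid) != 1L || !is.finite(grid) || grid <= 0)
    stop("grid must be a single positive time step", call. = FALSE)
  sort(unique(c(seq(0, t_end, by = grid), breaks, t_end)))
}

check_init <- function(init, nms) {
  if (is.null(init)) init <- stats::setNames(rep(0, length(nms)), nms)
  if (length(init) != length(nms) || any(!is.finite(init)) || any(init < 0))
    stop("init must be ", length(nms),
         " finite nonnegative values (", paste(nms, collapse = ", "), ")",
         call. = FALSE)
  stats::setNames(as.numeric(init), nms)
}

new_trajectory <- function(df, model_id, params, prog, sw = NULL) {
  structure(df, class = c("myc_trajectory", "data.frame"),
            model_id = model_id, params = params, prog = prog, sw = sw)
}

#' Simulate Model 1: FBXW7-mediated, phosphorylation-dependent degradation
#'
#' Integrates the five-state system (x1, x2, x3, x4, active FBXW7 F*)
#' driven by the pulsed Erk/GSK3beta signals and constant growth factor:
#' \deqn{dx_1/dt = k_1 GF - k_2 x_1 - k_3 E x_1}
#' \deqn{dx_2/dt = k_3 E x_1 - k_4 x_2 - k_5 G x_2}
#' \deqn{dx_3/dt = k_5 G x_2 - k_6 x_3 - k_7 F^* x_3 + k_{10} x_4}
#' \deqn{dx_4/dt = k_7 F^* x_3 - (k_{10} + k_{11}) x_4}
#' \deqn{dF^*/dt = k_8 x_3 (F_T - F^*) - k_9 F^*}
#'
#' Integration restarts at every signal discontinuity. The ubiquitinated
#' fraction gamma = x4 / (x1 + x2 + x3 + x4) is attached per time point.
#'
#' @param params A [rate_parameters()] object.
#' @param prog A [signal_program()].
#' @param t_end Horizon (h).
#' @param init Initial state `(x1, x2, x3, x4, Fstar)`; defaults to all
#'   zeros (no c-Myc and no active ligase before growth-factor stimulation).
#' @param grid Output time step (h); breakpoints are always included.
#' @param rtol,atol Solver tolerances.
#' @return A `myc_trajectory` data frame with columns `time`, the states,
#'   `gamma`, and the signal levels.
#' @examples
#' traj <- simulate_model1()
#' model_output(traj)
#' @export
simulate_model1 <- function(params = rate_parameters(),
                            prog = signal_program(),
                            t_end = 30, init = NULL, grid = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_parameters"), inherits(prog, "signal_program"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  y0 <- check_init(init, c("x1", "x2", "x3", "x4", "Fstar"))
  bks <- signal_breakpoints(prog, NULL, t_end)
  times <- make_time_grid(t_end, grid, bks)
  k <- as.numeric(params)[1:11]
  parms_for <- function(t0) c(k, prog$GF, prog$F_T,
                              erk_signal(t0, prog), gsk_signal(t0, prog))
  out <- integrate_piecewise(y0, times, bks, "mycdeg_deriv1", "mycdeg_init1",
                             parms_for, rtol, atol)
  df <- data.frame(time = out[, 1], x1 = out[, 2], x2 = out[, 3],
                   x3 = out[, 4], x4 = out[, 5], Fstar = out[, 6])
  tot <- df$x1 + df$x2 + df$x3 + df$x4
  df$gamma <- ifelse(tot > 0, df$x4 / tot, 0)
  df$signal_E <- erk_signal(df$time, prog)
  df$signal_G <- gsk_signal(df$time, prog)
  new_trajectory(df, "model1", params, prog)
}

#' Simulate Model 2: Skp2-mediated, phosphorylation-independent degradation
#'
#' Integrates the three-state system (x1, x4, Skp2 S):
#' \deqn{dx_1/dt = k_1 GF - k_2 x_1 - k_{12} x_1 S}
#' \deqn{dx_4/dt = k_{12} x_1 S - k_{11} x_4}
#' \deqn{dS/dt = k_{13} x_1 - k_{14} S}
#'
#' The two-pool ubiquitinated fraction gamma' = x4 / (x1 + x4) is attached.
#'
#' @inheritParams simulate_model1
#' @param init Initial state `(x1, x4, S)`; defaults to zeros.
#' @return A `myc_trajectory` data frame.
#' @export
simulate_model2 <- function(params = rate_parameters(),
                            prog = signal_program(),
                            t_end = 30, init = NULL, grid = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_parameters"), inherits(prog, "signal_program"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  y0 <- check_init(init, c("x1", "x4", "S"))
  times <- make_time_grid(t_end, grid, t_end)
  k <- as.numeric(params)
  parms <- c(k[1], k[2], k[11], k[12], k[13], k[14], prog$GF)
  out <- integrate_piecewise(y0, times, t_end, "mycdeg_deriv2", "mycdeg_init2",
                             function(t0) parms, rtol, atol)
  df <- data.frame(time = out[, 1], x1 = out[, 2], x4 = out[, 3], S = out[, 4])
  tot <- df$x1 + df$x4
  df$gamma <- ifelse(tot > 0, df$x4 / tot, 0)
  new_trajectory(df, "model2", params, prog)
}

#' Simulate the combined model with the exclusivity switch
#'
#' The six-state union of Models 1 and 2 in which the binary switch
#' alpha(t) selects which E3 adaptor is being activated:
#' \deqn{dF^*/dt = \alpha k_8 x_3 (F_T - F^*) - k_9 F^*}
#' \deqn{dS/dt = (1 - \alpha) k_{13} x_1 - k_{14} S}
#' with the x1 and x4 balances carrying both ubiquitination routes.
#' `sw = NULL` requests the no-switch variant in which both activation
#' terms are simultaneously on (alpha-factors replaced by 1).
#'
#' @inheritParams simulate_model1
#' @param sw A [switch_structure()], or `NULL` for the no-switch variant.
#' @param init Initial state `(x1, x2, x3, x4, Fstar, S)`; defaults to zeros.
#' @return A `myc_trajectory` data frame including an `alpha` column
#'   (`NA` for the no-switch variant).
#' @examples
#' both <- simulate_combined(sw = NULL)       # both adaptors active
#' swd <- simulate_combined(sw = switch_structure(t_on = 3, duration = 27))
#' objective_J(swd) < objective_J(both)
#' @export
simulate_combined <- function(params = rate_parameters(),
                              prog = signal_program(),
                              sw = switch_structure(),
                              t_end = 30, init = NULL, grid = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_parameters"), inherits(prog, "signal_program"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (!is.null(sw)) stopifnot(inherits(sw, "switch_structure"))
  y0 <- check_init(init, c("x1", "x2", "x3", "x4", "Fstar", "S"))
  bks <- signal_breakpoints(prog, sw, t_end)
  times <- make_time_grid(t_end, grid, bks)
  k <- as.numeric(params)
  parms_for <- function(t0) {
    a <- if (is.null(sw)) NA_real_ else alpha_signal(t0, sw)
    aF <- if (is.null(sw)) 1 else a
    aS <- if (is.null(sw)) 1 else 1 - a
    c(k, prog$GF, prog$F_T, erk_signal(t0, prog), gsk_signal(t0, prog), aF, aS)
  }
  out <- integrate_piecewise(y0, times, bks, "mycdeg_derivc", "mycdeg_initc",
                             parms_for, rtol, atol)
  df <- data.frame(time = out[, 1], x1 = out[, 2], x2 = out[, 3],
                   x3 = out[, 4], x4 = out[, 5], Fstar = out[, 6], S = out[, 7])
  tot <- df$x1 + df$x2 + df$x3 + df$x4
  df$gamma <- ifelse(tot > 0, df$x4 / tot, 0)
  df$signal_E <- erk_signal(df$time, prog)
  df$signal_G <- gsk_signal(df$time, prog)
  df$alpha <- if (is.null(sw)) NA_real_ else alpha_signal(df$time, sw)
  new_trajectory(df, "combined", params, prog, sw)
}

#' @export
print.myc_trajectory <- function(x, ...) {
  cat(sprintf("<myc_trajectory> %s, %d time points over [%g, %g] h\n",
              attr(x, "model_id"), nrow(x), x$time[1], x$time[nrow(x)]))
  cat(sprintf("  final gamma = %.4f\n", x$gamma[nrow(x)]))
  invisible(x)
}

#' Write a trajectory to a tidy CSV file
#'
#' @param traj A `myc_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "myc_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
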