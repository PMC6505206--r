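## Decision process: random-search optimization of the exclusivity switch
## alpha(t) in the combined model, minimizing the accumulated ubiquitinated
## c-Myc J = int_0^T x4 dt.

#' Random-search optimization of the exclusivity switch
#'
#' Draws `n_iter` switch structures with switch-on time and duration
#' uniform over the horizon (via [sample_switch_structures()]), simulates
#' the combined model for each, evaluates the objective
#' `J = int_0^T x4(t) dt`, and returns all candidates with the argmin.
#' Two boundary probes are always appended after the random candidates:
#' alpha always on (`t_on = 0`, `duration = T_end`) and alpha always off
#' (`duration = 0`), so the returned optimum dominates both pure
#' strategies by construction. Ties in J are broken by the earliest
#' candidate index. Pure i.i.d. random search, no refinement: the
#' reported optimum is exactly the best sampled structure.
#'
#' @param params [rate_parameters()] for the combined model.
#' @param prog [signal_program()].
#' @param n_iter Number of random candidates.
#' @param T_end Horizon (h).
#' @param seed Integer seed.
#' @param grid Trajectory time step used for the trapezoidal J (h).
#' @return An object of class `switch_optimization`: list with
#'   `candidates` (data frame: iteration, t_on, duration, J), `best`
#'   (switch structure), `best_J`, `best_index`, `J_profile`, `seed`.
#' @examples
#' \donttest{
#' run <- optimize_switch(n_iter = 200, seed = 1)
#' summarize_switch(run)
#' }
#' @export
optimize_switch <- function(params = rate_parameters(),
                            prog = signal_program(),
                            n_iter = 10000, T_end = 30, seed = 1,
                            grid = 0.1) {
  stopifnot(inherits(params, "rate_parameters"), inherits(prog, "signal_program"))
  if (!is.numeric(n_iter) || n_iter < 1)
    stop("n_iter must be at least 1", call. = FALSE)
  sws <- sample_switch_structures(n_iter, T_end = T_end, seed = seed)
  sws <- c(sws, list(switch_structure(0, T_end, T_end),       # alpha == 1
                     switch_structure(0, 0, T_end)))          # alpha == 0
  J <- rep(NA_real_, length(sws))
  for (i in seq_along(sws)) {
    J[i] <- tryCatch(
      objective_J(simulate_combined(params, prog, sw = sws[[i]],
                                    t_end = T_end, grid = grid)),
      error = function(e) NA_real_)
  }
  if (all(!is.finite(J)))
    stop("optimize_switch: every candidate simulation failed", call. = FALSE)
  best_i <- which.min(ifelse(is.finite(J), J, Inf))  # which.min: first min wins
  cand <- data.frame(iteration = seq_along(sws),
                     t_on = vapply(sws, `[[`, numeric(1), "t_on"),
                     duration = vapply(sws, `[[`, numeric(1), "duration"),
                     J = J)
  structure(list(candidates = cand, best = sws[[best_i]],
                 best_J = J[best_i], best_index = best_i,
                 J_profile = J, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), T_end = T_end,
                 params = params, prog = prog, grid = grid),
            class = "switch_optimization")
}

#' @export
print.switch_optimization <- function(x, ...) {
  cat(sprintf("<switch_optimization> %d candidates (+2 probes), seed %d\n",
              x$n_iter, x$seed))
  cat(sprintf("  best: alpha off until %.2f h, on for %.2f h, J = %.4f\n",
              x$best$t_on, min(x$best$duration, x$T_end - x$best$t_on),
              x$best_J))
  invisible(x)
}

#' Summarize the optimal switch against the no-switch combined model
#'
#' Reports the best switch-on time, duration and J, re-simulates the best
#' candidate and the no-switch variant (both adaptors simultaneously
#' active) at the same parameters, and compares their final ubiquitinated
#' levels.
#'
#' @param run A `switch_optimization`.
#' @return List with `t_on`, `duration`, `t_off` (effective end of the
#'   on-window), `J`, `x4_end_best`, `x4_end_noswitch`, `attenuated`
#'   (logical: best run ends below the no-switch run), and the two
#'   trajectories.
#' @export
summarize_switch <- function(run) {
  stopifnot(inherits(run, "switch_optimization"))
  best_traj <- simulate_combined(run$params, run$prog, sw = run$best,
                                 t_end = run$T_end, grid = run$grid)
  noswitch <- simulate_combined(run$params, run$prog, sw = NULL,
                                t_end = run$T_end, grid = run$grid)
  x4b <- best_traj$x4[nrow(best_traj)]
  x4n <- noswitch$x4[nrow(noswitch)]
  list(t_on = run$best$t_on,
       duration = run$best$duration,
       t_off = min(run$best$t_on + run$best$duration, run$T_end),
       J = run$best_J,
       x4_end_best = x4b,
       x4_end_noswitch = x4n,
       attenuated = x4b < x4n,
       best_trajectory = best_traj,
       noswitch_trajectory = noswitch)
}

#' Write the J profile of a switch search to CSV
#'
#' One row per candidate (iteration, t_on, duration, J), probes included.
#'
#' @param run A `switch_optimization`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_switch_profile <- function(run, path) {
  stopifnot(inherits(run, "switch_optimization"))
  utils::write.csv(run$candidates, path, row.names = FALSE)
  invisible(path)
}
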