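#' Pulsed input signal program
#'
#' Bundles the shape parameters of the pulsed Erk and GSK3beta inputs, the
#' constant growth-factor level and the total FBXW7 pool. All quantities are
#' dimensionless concentrations except the durations, which are hours.
#'
#' With the default amplitudes (baseline 0.1, pulse 0.9) the peak level of
#' either kinase signal is exactly 1.0. Erk is on over `[0, Dur_E)`.
#' GSK3beta is the sum of a boxcar centred on `Dur_G1` with full width
#' `1/Width_G` — under the defaults `[1, 3)`, turning on exactly as Erk
#' turns off — and a sustained step from `Dur_G2` onwards (see
#' [gsk_signal()]). Pulses are half-open on the right, so a signal is
#' already off at its own switch-off time.
#'
#' @param E_R Erk baseline level.
#' @param E_Max Erk pulse amplitude above baseline.
#' @param Dur_E Erk switch-off time (h); also the GSK3beta first switch-on.
#' @param G_R GSK3beta baseline level.
#' @param G_Max GSK3beta pulse amplitude above baseline.
#' @param Dur_G1 End of the first GSK3beta pulse (h).
#' @param Dur_G2 Start of the second, sustained GSK3beta pulse (h).
#' @param Width_G GSK3beta boxcar width factor (recorded, dimensionless).
#' @param GF Constant growth-factor level.
#' @param F_T Total FBXW7 pool.
#' @return An object of class `signal_program`.
#' @examples
#' prog <- signal_program()
#' erk_signal(0.5, prog)   # 1.0: pulse on
#' gsk_signal(4, prog)     # 0.1: between the two GSK3beta pulses
#' @export
signal_program <- function(E_R = 0.1, E_Max = 0.9, Dur_E = 1.0,
                           G_R = 0.1, G_Max = 0.9,
                           Dur_G1 = 2.0, Dur_G2 = 7.0, Width_G = 0.5,
                           GF = 1.0, F_T = 5.0) {
  prog <- list(E_R = E_R, E_Max = E_Max, Dur_E = Dur_E,
               G_R = G_R, G_Max = G_Max,
               Dur_G1 = Dur_G1, Dur_G2 = Dur_G2, Width_G = Width_G,
               GF = GF, F_T = F_T)
  for (nm in names(prog)) {
    v <- prog[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("signal_program: field '", nm,
           "' must be a single finite nonnegative number", call. = FALSE)
  }
  if (prog$Dur_G1 >= prog$Dur_G2)
    stop("signal_program: Dur_G1 must be smaller than Dur_G2", call. = FALSE)
  structure(prog, class = "signal_program")
}

#' @export
print.signal_program <- function(x, ...) {
  cat("<signal_program>\n")
  cat(sprintf("  Erk:      %.3g + %.3g on [0, %.3g) h\n", x$E_R, x$E_Max, x$Dur_E))
  w <- gsk_boxcar_window(x)
  cat(sprintf("  GSK3beta: %.3g + %.3g on [%.3g, %.3g) U [%.3g, Inf) h\n",
              x$G_R, x$G_Max, w[1], w[2], x$Dur_G2))
  cat(sprintf("  GF = %.3g, F_T = %.3g, Width_G = %.3g\n", x$GF, x$F_T, x$Width_G))
  invisible(x)
}

#' Binary switch structure for the combined model
#'
#' Describes one on-window of the exclusivity switch alpha(t): alpha is 1 on
#' `[t_on, min(t_on + duration, T_end))` and 0 elsewhere. alpha = 1 routes
#' degradation through FBXW7 activation, alpha = 0 through Skp2 activation.
#'
#' @param t_on Switch-on time (h), within `[0, T_end]`.
#' @param duration Length of the on-window (h), clipped at the horizon.
#' @param T_end Observation horizon (h).
#' @return An object of class `switch_structure`.
#' @examples
#' sw <- switch_structure(t_on = 3, duration = 27)
#' alpha_signal(2, sw)  # 0
#' alpha_signal(5, sw)  # 1
#' @export
switch_structure <- function(t_on = 0, duration = 30, T_end = 30) {
  if (!is.numeric(t_on) || length(t_on) != 1L || !is.finite(t_on))
    stop("switch_structure: t_on must be a single finite number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration < 0)
    stop("switch_structure: duration must be a single finite nonnegative number",
         call. = FALSE)
  if (!is.numeric(T_end) || length(T_end) != 1L || !is.finite(T_end) || T_end <= 0)
    stop("switch_structure: T_end must be a single positive number", call. = FALSE)
  if (t_on < 0 || t_on > T_end)
    stop("switch_structure: t_on must lie in [0, T_end]", call. = FALSE)
  structure(list(t_on = t_on, duration = duration, T_end = T_end),
            class = "switch_structure")
}

#' @export
print.switch_structure <- function(x, ...) {
  cat(sprintf("<switch_structure> alpha = 1 on [%.3g, %.3g) h (horizon %.3g h)\n",
              x$t_on, min(x$t_on + x$duration, x$T_end), x$T_end))
  invisible(x)
}

#' Heaviside step function
#'
#' Unit step with the half-open convention `theta(0) = 0`, so that pulses
#' built from it are on over `[on, off)` intervals: a signal is already off
#' at its own switch-off instant, and the Erk pulse hands over to GSK3beta
#' at `t = Dur_E` without a double-on instant.
#'
#' @param x Numeric vector of finite values.
#' @return 0/1 vector: 1 where `x > 0`, 0 otherwise.
#' @examples
#' heaviside(c(-1, 0, 2))  # 0 0 1
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("heaviside: input must be finite numeric", call. = FALSE)
  as.numeric(x > 0)
}

#' Erk input signal E(t)
#'
#' `E(t) = E_R + E_Max * theta(Dur_E - t)`: a single rectangular pulse at
#' `E_R + E_Max` over `[0, Dur_E)` on a constant baseline `E_R`.
#'
#' @param t Time (h), nonnegative; vectorized.
#' @param prog A [signal_program()].
#' @return Signal level(s) in `[E_R, E_R + E_Max]`.
#' @export
erk_signal <- function(t, prog = signal_program()) {
  stopifnot(inherits(prog, "signal_program"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("erk_signal: t must be finite and nonnegative", call. = FALSE)
  prog$E_R + prog$E_Max * heaviside(prog$Dur_E - t)
}

#' GSK3beta input signal G(t)
#'
#' `G(t) = G_R + G_Max (pi[Width_G (Dur_G1 - t)] + theta(t - Dur_G2))`,
#' where `pi[u]` is the unit rectangle (1 for `|u| < 1/2`, half-open on
#' the right like every pulse here). The boxcar is therefore centred on
#' `Dur_G1` with full width `1/Width_G`: with the defaults
#' (`Dur_G1 = 2`, `Width_G = 0.5`) the first GSK3beta pulse occupies
#' `[1, 3)` h — it turns on exactly as the Erk pulse ends — and the second,
#' sustained pulse runs from `Dur_G2 = 7` h to the end of the course. If a
#' perturbed program makes the two windows overlap they are merged (the
#' amplitude is never added twice).
#'
#' @inheritParams erk_signal
#' @return Signal level(s) in `[G_R, G_R + G_Max]`.
#' @export
gsk_signal <- function(t, prog = signal_program()) {
  stopifnot(inherits(prog, "signal_program"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("gsk_signal: t must be finite and nonnegative", call. = FALSE)
  w <- gsk_boxcar_window(prog)
  on1 <- t >= w[1] & t < w[2]
  on2 <- t >= prog$Dur_G2
  prog$G_R + prog$G_Max * as.numeric(on1 | on2)
}

## The first GSK3beta window [Dur_G1 - 1/(2 Width_G), Dur_G1 + 1/(2 Width_G)),
## clipped below at 0. Width_G = 0 would mean an infinitely wide boxcar; it
## is rejected at construction time for perturbed programs via the
## nonnegativity check plus this guard.
gsk_boxcar_window <- function(prog) {
  if (prog$Width_G <= 0)
    stop("gsk_signal: Width_G must be positive", call. = FALSE)
  half <- 1 / (2 * prog$Width_G)
  c(max(0, prog$Dur_G1 - half), prog$Dur_G1 + half)
}

#' Exclusivity switch alpha(t)
#'
#' Binary switching function of the combined model: 1 inside the on-window
#' of `sw`, 0 elsewhere (half-open on the right, like all pulses here).
#'
#' @param t Time (h) within `[0, T_end]`; vectorized.
#' @param sw A [switch_structure()].
#' @return 0/1 vector.
#' @export
alpha_signal <- function(t, sw) {
  stopifnot(inherits(sw, "switch_structure"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("alpha_signal: t must be finite numeric", call. = FALSE)
  if (any(t < 0 | t > sw$T_end))
    stop("alpha_signal: t must lie in [0, T_end]", call. = FALSE)
  t_off <- min(sw$t_on + sw$duration, sw$T_end)
  as.numeric(t >= sw$t_on & t < t_off)
}

#' Discontinuity times of the input signals
#'
#' All times at which E(t), G(t) or alpha(t) jumps, within `[0, t_end]`.
#' The integrator restarts at each of these so the solver never steps
#' across a discontinuity.
#'
#' @param prog A [signal_program()].
#' @param sw Optionally a [switch_structure()].
#' @param t_end Horizon (h).
#' @return Sorted unique times including 0 and `t_end`.
#' @export
signal_breakpoints <- function(prog = signal_program(), sw = NULL, t_end = 30) {
  stopifnot(inherits(prog, "signal_program"))
  bks <- c(0, prog$Dur_E, gsk_boxcar_window(prog), prog$Dur_G2, t_end)
  if (!is.null(sw)) {
    stopifnot(inherits(sw, "switch_structure"))
    bks <- c(bks, sw$t_on, min(sw$t_on + sw$duration, sw$T_end))
  }
  sort(unique(bks[bks >= 0 & bks <= t_end]))
}
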