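## Independent fixed-step RK4 reference integrator.
##
## Deliberately re-states the model right-hand sides and signal timetables
## in plain R, without touching the package's compiled derivatives or its
## piecewise lsoda driver, so that agreement between the two is a genuine
## cross-check. Steps are aligned to the signal breakpoints; within a
## segment the signals are constant so classical RK4 retains its full
## order.

oracle_E <- function(t, prog) prog$E_R + ifelse(t < prog$Dur_E, prog$E_Max, 0)
oracle_G <- function(t, prog) {
  half <- 1 / (2 * prog$Width_G)
  on <- (t >= max(0, prog$Dur_G1 - half) & t < prog$Dur_G1 + half) |
    t >= prog$Dur_G2
  prog$G_R + ifelse(on, prog$G_Max, 0)
}

oracle_deriv <- function(model, y, t, k, prog, alpha = NA) {
  E <- oracle_E(t, prog); G <- oracle_G(t, prog)
  if (model == "model1") {
    c(k[1] * prog$GF - k[2] * y[1] - k[3] * E * y[1],
      k[3] * E * y[1] - k[4] * y[2] - k[5] * G * y[2],
      k[5] * G * y[2] - k[6] * y[3] - k[7] * y[5] * y[3] + k[10] * y[4],
      k[7] * y[5] * y[3] - (k[10] + k[11]) * y[4],
      k[8] * y[3] * (prog$F_T - y[5]) - k[9] * y[5])
  } else if (model == "model2") {
    c(k[1] * prog$GF - k[2] * y[1] - k[12] * y[1] * y[3],
      k[12] * y[1] * y[3] - k[11] * y[2],
      k[13] * y[1] - k[14] * y[3])
  } else {
    aF <- if (is.na(alpha)) 1 else alpha
    aS <- if (is.na(alpha)) 1 else 1 - alpha
    c(k[1] * prog$GF - k[2] * y[1] - k[3] * E * y[1] - k[12] * y[1] * y[6],
      k[3] * E * y[1] - k[4] * y[2] - k[5] * G * y[2],
      k[5] * G * y[2] - k[6] * y[3] - k[7] * y[5] * y[3] + k[10] * y[4],
      k[7] * y[5] * y[3] - (k[10] + k[11]) * y[4] + k[12] * y[1] * y[6],
      aF * k[8] * y[3] * (prog$F_T - y[5]) - k[9] * y[5],
      aS * k[13] * y[1] - k[14] * y[6])
  }
}

## Integrate with RK4 at fixed step h, recording the state at `record`
## times (which must be breakpoint-aligned multiples of h or segment ends).
oracle_rk4 <- function(model, k, prog, y0, t_end, h = 1e-3,
                       record = seq(0, t_end, by = 1), sw = NULL) {
  ghalf <- 1 / (2 * prog$Width_G)
  segs <- sort(unique(c(0, prog$Dur_E, max(0, prog$Dur_G1 - ghalf),
                        prog$Dur_G1 + ghalf, prog$Dur_G2,
                        if (!is.null(sw)) c(sw$t_on,
                                            min(sw$t_on + sw$duration, sw$T_end)),
                        record, t_end)))
  segs <- segs[segs >= 0 & segs <= t_end]
  out <- matrix(NA_real_, nrow = length(record), ncol = length(y0))
  y <- y0
  if (any(record == 0)) out[record == 0, ] <- y
  for (i in seq_len(length(segs) - 1)) {
    a <- segs[i]; b <- segs[i + 1]
    if (b - a <= 0) next
    alpha <- if (is.null(sw)) NA
             else as.numeric(a >= sw$t_on &
                             a < min(sw$t_on + sw$duration, sw$T_end))
    nstep <- max(1L, ceiling((b - a) / h))
    hh <- (b - a) / nstep
    t <- a
    mid <- a + hh / 2   # signals constant in segment; any interior t works
    for (s in seq_len(nstep)) {
      k1v <- oracle_deriv(model, y, mid, k, prog, alpha)
      k2v <- oracle_deriv(model, y + hh / 2 * k1v, mid, k, prog, alpha)
      k3v <- oracle_deriv(model, y + hh / 2 * k2v, mid, k, prog, alpha)
      k4v <- oracle_deriv(model, y + hh * k3v, mid, k, prog, alpha)
      y <- y + hh / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      t <- t + hh
    }
    hit <- which(abs(record - b) < 1e-12)
    if (length(hit)) out[hit, ] <- y
  }
  list(times = record, states = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Plain trapezoid helper used by a few tests.
trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

## Minimal hand-built trajectory for output-function tests.
fake_trajectory <- function(time, x4, gamma = NULL, model_id = "model1") {
  df <- data.frame(time = time, x1 = 0, x2 = 0, x3 = 0, x4 = x4)
  df$gamma <- if (is.null(gamma)) 0 else gamma
  structure(df, class = c("myc_trajectory", "data.frame"), model_id = model_id)
}
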