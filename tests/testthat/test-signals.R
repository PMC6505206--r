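test_that("heaviside uses the half-open convention theta(0) = 0", {
  expect_equal(heaviside(2.0), 1)
  expect_equal(heaviside(-1.0), 0)
  expect_equal(heaviside(0.0), 0)
  expect_equal(heaviside(c(-3, 0, 1e-12)), c(0, 0, 1))
  expect_error(heaviside(NaN), "finite")
  expect_error(heaviside(Inf), "finite")
})

test_that("Erk pulse is on over [0, Dur_E) at unit peak and baseline after", {
  prog <- signal_program()
  expect_equal(erk_signal(0.5, prog), 1.0)
  expect_equal(erk_signal(1.5, prog), 0.1)
  expect_equal(erk_signal(1.0, prog), 0.1)  # off at its own switch-off time
  expect_error(erk_signal(-0.1, prog), "nonnegative")
})

test_that("GSK3beta is a boxcar about Dur_G1 plus a sustained late step", {
  prog <- signal_program()
  expect_equal(gsk_signal(1.5, prog), 1.0)   # boxcar [1, 3): on at 1 h
  expect_equal(gsk_signal(4.0, prog), 0.1)   # gap between pulses
  expect_equal(gsk_signal(10.0, prog), 1.0)  # sustained second pulse
  expect_equal(gsk_signal(0.5, prog), 0.1)   # before Erk hands over
  expect_equal(gsk_signal(2.9, prog), 1.0)   # still inside the boxcar
  expect_equal(gsk_signal(3.0, prog), 0.1)   # half-open right edge
  ## narrower width factor -> wider boxcar (full width 1/Width_G)
  wide <- signal_program(Width_G = 0.25)
  expect_equal(gsk_signal(c(0.1, 3.9), wide), c(1.0, 1.0))
  expect_equal(gsk_signal(4.0, wide), 0.1)
  expect_error(gsk_signal(-1, prog), "nonnegative")
})

test_that("signal peaks occupy exactly the documented windows on a dense grid", {
  prog <- signal_program()
  t <- seq(0, 30, by = 0.01)
  E <- erk_signal(t, prog)
  G <- gsk_signal(t, prog)
  expect_equal(E == 1.0, t < 1)
  expect_equal(G == 1.0, (t >= 1 & t < 3) | t >= 7)
  ## bounds: the boxcar and step terms never add up
  expect_true(all(E >= prog$E_R & E <= prog$E_R + prog$E_Max))
  expect_true(all(G >= prog$G_R & G <= prog$G_R + prog$G_Max))
})

test_that("overlapping perturbed GSK3beta windows merge instead of stacking", {
  prog <- signal_program(Dur_G1 = 6.9, Dur_G2 = 7)  # boxcar [5.9, 7.9) overlaps
  expect_equal(max(gsk_signal(seq(0, 30, 0.05), prog)), 1.0)
})

test_that("alpha switch is 1 exactly inside the clipped on-window", {
  sw <- switch_structure(t_on = 3, duration = 27, T_end = 30)
  expect_equal(alpha_signal(2, sw), 0)
  expect_equal(alpha_signal(5, sw), 1)
  expect_equal(alpha_signal(3, sw), 1)
  expect_error(alpha_signal(31, sw), "T_end")
  expect_error(alpha_signal(-1, sw), "T_end")
  off <- switch_structure(t_on = 10, duration = 0)
  expect_equal(alpha_signal(seq(0, 30, 0.5), off), rep(0, 61))
  clip <- switch_structure(t_on = 25, duration = 10, T_end = 30)
  expect_equal(alpha_signal(29.9, clip), 1)
})

test_that("signal program and switch structures validate their fields", {
  expect_error(signal_program(E_R = -0.1), "E_R")
  expect_error(signal_program(Dur_G1 = 8, Dur_G2 = 7), "Dur_G1")
  expect_error(switch_structure(t_on = -1), "t_on")
  expect_error(switch_structure(t_on = 31, T_end = 30), "t_on")
  expect_error(switch_structure(duration = -2), "duration")
  prog <- signal_program()
  expect_equal(prog$E_R + prog$E_Max, 1.0)  # unit peak amplitude
  expect_equal(prog$G_R + prog$G_Max, 1.0)
})

test_that("breakpoints enumerate every discontinuity once, sorted", {
  prog <- signal_program()
  sw <- switch_structure(t_on = 3.5, duration = 24)
  bks <- signal_breakpoints(prog, sw, t_end = 30)
  expect_equal(bks, c(0, 1, 3, 3.5, 7, 27.5, 30))
  expect_equal(signal_breakpoints(prog, NULL, 30), c(0, 1, 3, 7, 30))
  ## switch times beyond the horizon are dropped
  expect_equal(signal_breakpoints(prog, switch_structure(29, 10), 10),
               c(0, 1, 3, 7, 10))
})
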