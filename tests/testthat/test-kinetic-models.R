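params <- rate_parameters()
prog <- signal_program()

test_that("zero forcing and zero state stay identically zero", {
  p0 <- rate_parameters(k1 = 0)
  traj <- simulate_model1(p0, signal_program(GF = 0), grid = 0.5)
  expect_true(all(abs(as.matrix(traj[, c("x1", "x2", "x3", "x4", "Fstar")])) < 1e-12))
  expect_true(all(traj$gamma == 0))
})

test_that("no FBXW7 activation means no ubiquitination in Model 1", {
  p <- rate_parameters(k8 = 0)
  traj <- simulate_model1(p, prog, grid = 0.25)
  expect_true(all(traj$Fstar == 0))
  expect_true(all(traj$x4 == 0))
})

test_that("Model 2 with no Skp2 binding reduces to linear synthesis-decay", {
  p <- rate_parameters(k12 = 0)
  traj <- simulate_model2(p, prog, grid = 0.25)
  expect_true(all(traj$x4 == 0))
  ## x1 approaches k1*GF/k2 monotonically from below
  lim <- as.numeric(p)[1] * prog$GF / as.numeric(p)[2]
  expect_true(all(diff(traj$x1) > -1e-12))
  expect_true(all(traj$x1 <= lim + 1e-9))
  expect_equal(traj$x1[nrow(traj)], lim * (1 - exp(-as.numeric(p)[2] * 30)),
               tolerance = 1e-7)
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  rec <- seq(0, 30, by = 1)
  k <- as.numeric(params)

  traj1 <- simulate_model1(params, prog, grid = 1)
  ref1 <- oracle_rk4("model1", k, prog, rep(0, 5), 30, h = 1e-3, record = rec)
  got1 <- as.matrix(traj1[match(rec, traj1$time), c("x1", "x2", "x3", "x4", "Fstar")])
  expect_lt(max(abs(got1 - ref1$states)), 1e-4)

  traj2 <- simulate_model2(params, prog, grid = 1)
  ref2 <- oracle_rk4("model2", k, prog, rep(0, 3), 30, h = 1e-3, record = rec)
  got2 <- as.matrix(traj2[match(rec, traj2$time), c("x1", "x4", "S")])
  expect_lt(max(abs(got2 - ref2$states)), 1e-4)

  sw <- switch_structure(t_on = 3, duration = 27)
  trajc <- simulate_combined(params, prog, sw = sw, grid = 1)
  refc <- oracle_rk4("combined", k, prog, rep(0, 6), 30, h = 1e-3,
                     record = rec, sw = sw)
  gotc <- as.matrix(trajc[match(rec, trajc$time),
                          c("x1", "x2", "x3", "x4", "Fstar", "S")])
  expect_lt(max(abs(gotc - refc$states)), 1e-4)
})

test_that("combined model reduces to Model 1 when alpha is always on", {
  sw_on <- switch_structure(t_on = 0, duration = 30)
  tc <- simulate_combined(params, prog, sw = sw_on, grid = 0.25,
                          rtol = 1e-10, atol = 1e-12)
  t1 <- simulate_model1(params, prog, grid = 0.25, rtol = 1e-10, atol = 1e-12)
  expect_true(all(tc$S == 0))
  for (col in c("x1", "x2", "x3", "x4", "Fstar"))
    expect_lt(max(abs(tc[[col]] - t1[[col]])), 1e-8)
})

test_that("combined model reduces to Model 2 when alpha is off and the
           phosphorylation branch is silenced", {
  ## Without deubiquitination (k10 = 0) no flux can leak from the Skp2-made
  ## x4 back into the phosphorylation branch, so the reduction is exact.
  p <- rate_parameters(k10 = 0)
  silent <- signal_program(E_R = 0, E_Max = 0, G_R = 0, G_Max = 0)
  sw_off <- switch_structure(t_on = 0, duration = 0)
  tc <- simulate_combined(p, silent, sw = sw_off, grid = 0.25,
                          rtol = 1e-10, atol = 1e-12)
  t2 <- simulate_model2(p, silent, grid = 0.25, rtol = 1e-10, atol = 1e-12)
  expect_true(all(tc$x2 == 0) && all(tc$x3 == 0) && all(tc$Fstar == 0))
  for (col in c("x1", "x4", "S"))
    expect_lt(max(abs(tc[[col]] - t2[[col]])), 1e-8)
})

test_that("states stay nonnegative and FBXW7 stays within its pool", {
  set.seed(20260926)
  for (i in 1:100) {
    k <- as.list(stats::setNames(exp(stats::runif(14, log(0.05), log(5))),
                                 paste0("k", 1:14)))
    p <- do.call(rate_parameters, k)
    traj <- simulate_combined(p, prog, sw = switch_structure(
      t_on = stats::runif(1, 0, 30), duration = stats::runif(1, 0, 30)),
      grid = 0.5)
    states <- as.matrix(traj[, c("x1", "x2", "x3", "x4", "Fstar", "S")])
    expect_gt(min(states), -1e-9)
    expect_lt(max(traj$Fstar), prog$F_T + 1e-9)
  }
})

test_that("gamma_fraction covers both pool conventions and edge cases", {
  expect_equal(gamma_fraction(c(x1 = 1, x2 = 1, x3 = 1, x4 = 1)), 0.25)
  expect_equal(gamma_fraction(c(x1 = 3, x2 = 2, x3 = 1, x4 = 0)), 0)
  expect_equal(gamma_fraction(c(x1 = 0, x2 = 0, x3 = 0, x4 = 2)), 1)
  expect_equal(gamma_fraction(c(x1 = 0, x2 = 0, x3 = 0, x4 = 0)), 0)
  expect_equal(gamma_fraction(c(x1 = 1, x4 = 1), mode = "two_pool"), 0.5)
  expect_equal(gamma_fraction(c(x1 = 0, x4 = 0), mode = "two_pool"), 0)
  expect_error(gamma_fraction(c(x1 = -1, x2 = 0, x3 = 0, x4 = 1)), "nonnegative")
})

test_that("model_output is the trajectory's final ubiquitinated fraction", {
  traj <- simulate_model1(params, prog, grid = 0.5)
  last <- traj[nrow(traj), ]
  expect_identical(model_output(traj),
                   gamma_fraction(c(x1 = last$x1, x2 = last$x2,
                                    x3 = last$x3, x4 = last$x4)))
  expect_equal(model_output(fake_trajectory(0:30, 0, gamma = 0.4)), 0.4)
  expect_error(model_output(fake_trajectory(0, 0)), "truncated")
})

test_that("objective J reproduces closed-form integrals", {
  t <- seq(0, 30, by = 0.5)
  expect_equal(objective_J(fake_trajectory(t, rep(0, length(t)))), 0)
  expect_equal(objective_J(fake_trajectory(t, rep(2, length(t)))), 60)
  expect_equal(objective_J(fake_trajectory(t, t)), 450)  # linear ramp, exact
  expect_error(objective_J(fake_trajectory(0, 0)), "grid")
})

test_that("trajectory grid covers [0, t_end] and honors breakpoints", {
  traj <- simulate_model1(params, prog, grid = 0.25)
  expect_equal(traj$time[1], 0)
  expect_equal(traj$time[nrow(traj)], 30)
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(c(1, 2, 7) %in% traj$time))
  expect_true(all(traj$gamma >= 0 & traj$gamma <= 1))
})

test_that("phospho-pools appear only after the Erk pulse hands over", {
  traj <- simulate_model1(params, prog, grid = 0.05)
  early <- traj$time <= 1
  ## x1 + x2 grows steeply while Erk is on
  pool12 <- traj$x1 + traj$x2
  expect_true(all(diff(pool12[early]) > 0))
  ## x3, x4 appear only after GSK3beta takes over at 1 h: their peaks come
  ## later and the level reached before 1 h is a small fraction of the peak
  ## (the baseline G_R = G_Max/9 leaks a little x3 before the pulse, the
  ## doubly-lagged x4 even less)
  expect_lt(max(traj$x3[early]), 0.2 * max(traj$x3))
  expect_lt(max(traj$x4[early]), 0.1 * max(traj$x4))
  expect_gt(traj$time[which.max(traj$x3)], 1)
  expect_gt(traj$time[which.max(traj$x4)], 1)
  after <- traj$time > 2 & traj$time < 7
  expect_gt(max(traj$x3[after]), 0.01)
  expect_gt(max(traj$x4[after]), 0.01)
})
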