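params <- rate_parameters()
prog <- signal_program()

test_that("zero perturbation intensity reproduces the nominal set exactly", {
  ens <- sample_parameters(params, prog, intensity = 0, n = 5, seed = 3)
  expect_true(all(apply(ens$samples, 1, function(r)
    all(r == ens$nominal))))
  ens <- run_ensemble(ens)
  nominal_out <- model_output(simulate_model1(params, prog, grid = 30))
  expect_true(all(ens$outputs == nominal_out))
})

test_that("Gaussian sampling is centred, positive and seed-reproducible", {
  n <- 5000
  ens <- sample_parameters(params, prog, intensity = 0.1, n = n, seed = 7)
  expect_true(all(ens$samples > 0))
  ## CLT bound: column means within 4 sigma / sqrt(n) of nominal
  bound <- 4 * 0.1 * ens$nominal / sqrt(n)
  expect_true(all(abs(colMeans(ens$samples) - ens$nominal) < bound))
  again <- sample_parameters(params, prog, intensity = 0.1, n = n, seed = 7)
  expect_identical(ens$samples, again$samples)
  other <- sample_parameters(params, prog, intensity = 0.1, n = n, seed = 8)
  expect_false(identical(ens$samples, other$samples))
})

test_that("parameter names are validated and mapped to the right nominals", {
  expect_error(sample_parameters(params, prog, param_names = c("k1", "bogus")),
               "bogus")
  ens <- sample_parameters(params, prog,
                           param_names = c("k5", "erk", "gsk", "gf"),
                           intensity = 0.1, n = 10, seed = 1)
  expect_equal(unname(ens$nominal),
               c(as.numeric(params)[5], prog$E_Max, prog$G_Max, prog$GF))
  expect_equal(ensemble_param_names("model2"),
               c("k1", "k2", "k11", "k12", "k13", "k14"))
  expect_true(all(c("Dur_E", "Dur_G1", "Dur_G2", "Width_G") %in%
                  ensemble_param_names("model1", robustness = TRUE)))
})

test_that("switch structures are uniform over the horizon and clipped", {
  sws <- sample_switch_structures(10000, T_end = 30, seed = 5)
  t_on <- vapply(sws, `[[`, numeric(1), "t_on")
  dur <- vapply(sws, `[[`, numeric(1), "duration")
  se <- 4 * (30 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(t_on) - 15), se)
  expect_lt(abs(mean(dur) - 15), se)
  expect_true(all(t_on >= 0 & t_on <= 30))
  t_off <- vapply(sws, function(s) min(s$t_on + s$duration, s$T_end), numeric(1))
  expect_true(all(t_off <= 30))
  again <- sample_switch_structures(10000, T_end = 30, seed = 5)
  expect_identical(sws, again)
})

test_that("running an ensemble fills bounded outputs row-independently", {
  ens <- sample_parameters(params, prog,
                           param_names = ensemble_param_names("model2"),
                           intensity = 0.15, n = 10, seed = 11,
                           model_id = "model2")
  ens <- run_ensemble(ens)
  expect_length(ens$outputs, 10)
  expect_true(all(is.finite(ens$outputs)))
  expect_true(all(ens$outputs >= 0 & ens$outputs <= 1))
  expect_true(all(ens$status == "ok"))
  ## permuting the rows permutes the outputs with them
  perm <- c(4, 1, 10, 3, 7, 2, 9, 5, 8, 6)
  ens2 <- ens
  ens2$samples <- ens$samples[perm, ]
  ens2$outputs <- NULL; ens2$status <- NULL
  ens2 <- run_ensemble(ens2)
  expect_equal(ens2$outputs, ens$outputs[perm], tolerance = 1e-12)
})

test_that("ensemble CSV round-trips through write_ensemble", {
  ens <- sample_parameters(params, prog,
                           param_names = ensemble_param_names("model2"),
                           intensity = 0.1, n = 5, seed = 2,
                           model_id = "model2")
  ens <- run_ensemble(ens)
  path <- tempfile(fileext = ".csv")
  write_ensemble(ens, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$output, ens$outputs, tolerance = 1e-12)
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(manifest$seed, 2)
  expect_equal(manifest$model_id, "model2")
})
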