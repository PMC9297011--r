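test_that("rate normalization follows the data-maximum convention", {
  ds <- data.frame(theta = c(0.2, 0.4, 0.6), T = 15, rate = c(2, 4, 8))
  expect_equal(normalize_rates(ds)$rate_norm, c(0.25, 0.5, 1))
  one <- data.frame(theta = 0.5, T = 15, rate = 3)
  expect_equal(normalize_rates(one)$rate_norm, 1)
  tie <- data.frame(theta = c(0.3, 0.6), T = 15, rate = c(5, 5))
  expect_equal(normalize_rates(tie)$rate_norm, c(1, 1))
  zero <- data.frame(theta = c(0.3, 0.6), T = 15, rate = 0)
  expect_error(normalize_rates(zero), "zero")
})

test_that("moisture fit round-trips noise-free synthetic data", {
  gt <- recovery_ground_truth()
  ds <- generate_respiration_dataset(gt, noise_model(sd = 0, seed = 1))
  fit <- fit_moisture_response(ds, fit_spec(seed = 1))
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-10)
  truth <- c(mu = 2, tau = 1, sigma = 1.5, psi_ref = 3)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
})

test_that("moisture fit rejects invalid designs", {
  gt <- recovery_ground_truth()
  ds <- generate_respiration_dataset(gt, noise_model(sd = 0, seed = 1),
                                     theta = c(0.2, 0.5, 0.8))
  expect_error(fit_moisture_response(ds), "distinct saturations")
  ds2 <- generate_respiration_dataset(gt, noise_model(sd = 0, seed = 1),
                                      theta = seq(0.1, 0.7, by = 0.1))
  expect_error(
    fit_moisture_response(ds2, fit_spec(free = c("mu", "tau", "sigma", "eps",
                                                 "A", "psi_ref", "scale"))),
    "under-determined")
  ds3 <- ds2; ds3$T <- rep(c(14, 16), length.out = nrow(ds3))
  expect_error(fit_moisture_response(ds3), "single temperature")
})

test_that("multistart selection is reproducible and never worse than any start", {
  gt <- recovery_ground_truth()
  ds <- generate_respiration_dataset(gt, noise_model(sd = 0.02, seed = 9))
  f1 <- fit_moisture_response(ds, fit_spec(seed = 4))
  f2 <- fit_moisture_response(ds, fit_spec(seed = 4))
  expect_identical(f1$estimates, f2$estimates)
  f3 <- fit_moisture_response(ds, fit_spec(seed = 4, n_starts = 3))
  expect_lte(f1$objective, f3$objective)
})

test_that("temperature prediction attenuates the pure Arrhenius response", {
  gt <- recovery_ground_truth()
  ds <- generate_respiration_dataset(gt, noise_model(sd = 0, seed = 2))
  fit <- fit_moisture_response(ds, fit_spec(seed = 2))
  pred <- predict_temperature_response(fit, Ea = 48000,
                                       T_grid = seq(5, 35, by = 5),
                                       Theta_fixed = 0.6)
  ratio <- pred$omega[pred$T == 35] / pred$omega[pred$T == 5]
  expect_lt(ratio, arrhenius_factor(48000, 5, 35))
  # near-dry limit: response approaches Arrhenius x solubility ratio
  pred0 <- predict_temperature_response(fit, Ea = 48000,
                                        T_grid = c(5, 35),
                                        Theta_fixed = 0.01)
  lim <- arrhenius_factor(48000, 5, 35) *
    saturated_o2(35) / saturated_o2(5)
  expect_equal(pred0$omega[2] / pred0$omega[1], lim, tolerance = 1e-3)
})

test_that("intrinsic Ea is recovered and exceeds the apparent Ea", {
  gt <- default_ground_truth()
  pars <- list(mu = 3, tau = 1, sigma = 1, eps = 0, A = 1, psi_ref = 0.8,
               gamma = 0, scale = 1, T_ref = 15, dialect = "standard")
  ea <- sapply(1:20, function(seed) {
    ds <- generate_respiration_dataset(gt, noise_model(sd = 0.02,
                                                       seed = 3000 + seed),
                                       theta = 0.6, T = seq(5, 35, by = 5),
                                       reps = 3)
    fit_intrinsic_Ea(ds, pars)$Ea
  })
  expect_lt(median(abs(ea - 48000)) / 48000, 0.05)
  # temperature-insensitive kinetics (Ea = 0) push the estimate to the
  # lower bound, which is flagged
  ds0 <- generate_respiration_dataset(default_ground_truth(Ea = 0),
                                      noise_model(sd = 0.005, seed = 3),
                                      theta = 0.6, T = seq(5, 35, by = 5),
                                      reps = 3)
  ef <- fit_intrinsic_Ea(ds0, pars)
  expect_true(ef$at_boundary)
  expect_lt(ef$Ea, 10000)
  # apparent Ea from the model's own temperature curve is attenuated
  pred <- predict_temperature_response(pars, Ea = 48000,
                                       T_grid = seq(5, 35, by = 2.5),
                                       Theta_fixed = 0.6)
  expect_lt(apparent_Ea(pred$T, pred$omega), 48000)
})
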