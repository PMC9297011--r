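test_that("potential demand is linear in microbes and saturating in carbon", {
  d <- demand_params(n_prime = 2, beta = 0.3, kappa = 0.5, v = 3,
                     Ea = 48000, C_D = 1, k_D = 1)
  expect_equal(potential_demand(demand_params(C_D = 0), 15), 0)
  # saturation limit: within 1% when C_D = 100 k_D
  d_sat <- demand_params(C_D = 100, k_D = 1)
  d_inf <- demand_params(C_D = 1e9, k_D = 1)
  expect_equal(potential_demand(d_sat, 15) / potential_demand(d_inf, 15), 1,
               tolerance = 0.01)
  d2 <- demand_params(n_prime = 4, beta = 0.3, kappa = 0.5, v = 3,
                      Ea = 48000, C_D = 1, k_D = 1)
  expect_equal(potential_demand(d2, 20), 2 * potential_demand(d, 20))
  # saturation slope multiplies demand by 1 + gamma * Theta
  dg <- demand_params(gamma = 2)
  expect_equal(potential_demand(dg, 15, Theta = 0.5),
               2 * potential_demand(dg, 15))
  # reference constructor reproduces k_ref exactly at T_ref
  dr <- demand_from_reference(k_ref = 0.37, T_ref = 15, Ea = 52000)
  expect_equal(potential_demand(dr, 15), 0.37)
  expect_equal(potential_demand(dr, 25) / potential_demand(dr, 15),
               arrhenius_factor(52000, 15, 25))
})

test_that("steady concentrations satisfy known algebraic reductions", {
  # k = 0: everything at saturation, no flux
  sc <- steady_concentrations(0, 1, 1, 1, 1, 1, 2)
  expect_equal(sc$c0, 2); expect_equal(sc$Co, 2); expect_equal(sc$Q, 0)
  # equal areas, k/alpha = 1, kL/D = 1 -> Co = Ceq/3, c0 = 2 Ceq/3
  sc <- steady_concentrations(k = 1, alpha = 1, D = 1, L = 1,
                              A_wa = 1, A_ws = 1, Ceq = 3)
  expect_equal(sc$Co, 1)
  expect_equal(sc$c0, 2)
  # dissolution resistance vanishes as alpha -> infinity
  sc <- steady_concentrations(k = 1, alpha = 1e12, D = 1, L = 1,
                              A_wa = 1, A_ws = 1, Ceq = 2)
  expect_equal(sc$Co, 1, tolerance = 1e-10)
  # sentinel: no interface with active demand
  sc <- steady_concentrations(k = 1, alpha = 1, D = 1, L = 1,
                              A_wa = 0, A_ws = 1, Ceq = 2)
  expect_equal(sc$Co, 0); expect_equal(sc$Q, 0)
  expect_error(steady_concentrations(1, 1, 1, 1, 0, 0, 1), "both")
})

test_that("O2 budget closes: dissolution = diffusion = uptake", {
  x <- draw_closure_inputs(1e4, seed = 101)
  sc <- do.call(steady_concentrations, x)
  dissolution <- x$alpha * x$A_wa * (x$Ceq - sc$c0)
  diffusion <- x$D * (sc$c0 - sc$Co) * (x$A_ws + x$A_wa) / (2 * x$L)
  uptake <- x$k * x$A_ws * sc$Co
  expect_lt(max(abs(dissolution - sc$Q) / sc$Q), 1e-10)
  expect_lt(max(abs(diffusion - sc$Q) / sc$Q), 1e-10)
  expect_lt(max(abs(uptake - sc$Q) / sc$Q), 1e-10)
  # concentration ordering holds everywhere
  expect_true(all(sc$Co >= 0 & sc$Co <= sc$c0 & sc$c0 <= x$Ceq * (1 + 1e-12)))
})

test_that("feedback factor limits and monotonicities", {
  expect_equal(feedback_factor(0, 1, 1, 1, 1, 1, "general"), 1)
  expect_equal(feedback_factor(0, 1, 1, 1, 1, 1, "dissolution_limited"), 1)
  # unit dimensionless group -> Er = 1/2 in the diffusion-limited form
  expect_equal(feedback_factor(k = 1, D = 1, L = 1, A_wa = 1, A_ws = 1,
                               regime = "diffusion_limited"), 0.5)
  # general converges to diffusion-limited as the dissolution group -> 0
  x <- draw_closure_inputs(200, seed = 5)
  eg <- feedback_factor(x$k, alpha = 1e6 * x$k * x$A_ws / x$A_wa,
                        x$D, x$L, x$A_wa, x$A_ws, "general")
  ed <- feedback_factor(x$k, Inf, x$D, x$L, x$A_wa, x$A_ws,
                        "diffusion_limited")
  expect_lt(max(abs(eg - ed) / ed), 1e-5)
  # Er falls with demand and distance, rises with diffusivity
  base <- list(k = 0.5, alpha = 2, D = 1, L = 1, A_wa = 1, A_ws = 1)
  er <- function(l) do.call(feedback_factor, c(l, list(regime = "general")))
  expect_lt(er(modifyList(base, list(k = 0.6))), er(base))
  expect_lt(er(modifyList(base, list(L = 1.2))), er(base))
  expect_gt(er(modifyList(base, list(D = 1.3))), er(base))
  expect_error(feedback_factor(1, 1, 1, 1, 1, 1, "magic"), "regime")
})

test_that("assembled respiration rate matches the printed closed form", {
  s <- open_structure()
  d <- demand_from_reference(k_ref = 0.2, T_ref = 15, Ea = 48000)
  out <- respiration_rate(seq(0, 1, by = 0.05), 15, s, d)
  direct <- omega_printed(out$Theta, k = 0.2, A_w = s$A_w,
                          A = s$A_a / s$A_w, lam = s$lam,
                          D = o2_diffusivity(15), Ceq = saturated_o2(15),
                          mu = s$mu, tau = s$tau, sigma = s$sigma,
                          eps = s$eps)
  expect_equal(out$omega, direct, tolerance = 1e-12)
  # endpoints
  expect_equal(out$omega[out$Theta == 0], 0)
  sc <- respiration_rate(1, 15, closed_structure(), d)
  expect_equal(sc$omega, 0) # closed soil, saturated: A_wa = 0 sentinel
  expect_equal(sc$Er, 0)
  # linear regime: Er -> 1 when demand is scaled down by 1e6
  d_small <- demand_from_reference(k_ref = 0.2e-6, T_ref = 15, Ea = 48000)
  o <- respiration_rate(0.6, 15, s, d_small)
  expect_gt(o$omega / (o$k * o$A_ws * o$Ceq), 0.999)
})

test_that("respiration curves normalize to a unit maximum", {
  s <- open_structure()
  d <- demand_from_reference(0.2)
  cv <- respiration_curve(seq(0, 1, length.out = 101), 15, s, d,
                          normalize = TRUE)
  expect_equal(max(cv$omega_norm), 1)
  # demand heterogeneity acts exactly through (1 + gamma Theta) and Er
  dg <- demand_from_reference(0.2, gamma = 3)
  c0 <- respiration_curve(seq(0.1, 0.9, 0.1), 15, s, d)
  cg <- respiration_curve(seq(0.1, 0.9, 0.1), 15, s, dg)
  expect_equal(cg$omega / c0$omega,
               (1 + 3 * c0$Theta) * cg$Er / c0$Er, tolerance = 1e-12)
  # open surface keeps respiration alive at full saturation
  expect_gt(respiration_rate(1, 15, s, d)$omega, 0)
  expect_error(respiration_curve(numeric(0), 15, s, d), "non-empty")
})
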