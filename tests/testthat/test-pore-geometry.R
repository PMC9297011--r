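test_that("interfacial areas honour the parametrization's endpoints and shape", {
  s <- closed_structure()
  a0 <- interfacial_areas(0, s)
  expect_equal(a0$A_wa, 0)
  expect_equal(a0$A_ws, 0)
  a1 <- interfacial_areas(1, s)
  expect_equal(a1$A_wa, 0) # eps = 0: no interface left at saturation
  expect_equal(a1$A_ws, s$A_w)
  # open surface: A_wa(1) = A_a * eps^sigma > 0
  so <- open_structure()
  expect_equal(interfacial_areas(1, so)$A_wa, so$A_a * so$eps^so$sigma)
  # with sigma = tau = 1 and eps = 0 the interfacial area peaks at 0.5
  grid <- seq(0, 1, by = 1e-4)
  awa <- interfacial_areas(grid, s)$A_wa
  expect_equal(grid[which.max(awa)], 0.5, tolerance = 1e-3)
  # wetted-wall area monotone non-decreasing for any valid params
  set.seed(7)
  for (i in 1:10) {
    sp <- structure_params(A_a = runif(1, 0.1, 5), A_w = runif(1, 0.1, 5),
                           eps = runif(1, 0, 0.2), sigma = runif(1, 0.1, 5),
                           tau = runif(1, 0.1, 5), mu = runif(1, 0.1, 5))
    expect_true(all(diff(interfacial_areas(grid, sp)$A_ws) >= 0))
    expect_true(all(interfacial_areas(grid, sp)$A_wa >= 0))
  }
  expect_error(interfacial_areas(1.2, s), "Theta")
})

test_that("hydraulic distance grows with saturation and hits its sentinels", {
  s <- closed_structure() # mu = 2, tau = 1: mu >= tau so L increases
  grid <- seq(0.05, 0.95, by = 0.01)
  L <- hydraulic_distance(grid, s)
  expect_true(all(diff(L) > 0))
  # where the two areas are numerically equal, L = lambda
  th_eq <- uniroot(function(x) {
    a <- interfacial_areas(x, s); a$A_ws - a$A_wa
  }, c(0.01, 0.99), tol = 1e-12)$root
  expect_equal(hydraulic_distance(th_eq, s), s$lam, tolerance = 1e-6)
  # closed soil at full saturation: infinite-resistance sentinel
  expect_identical(hydraulic_distance(1, s), Inf)
  expect_identical(hydraulic_distance(0, s), 0)
})

test_that("area-table fitting round-trips noise-free parameters", {
  s <- open_structure()
  tab <- generate_area_table(s, theta = seq(0.05, 0.95, by = 0.05),
                             noise = noise_model(sd = 0, seed = 1))
  fit <- fit_area_table(tab, seed = 3)
  expect_true(fit$converged)
  for (nm in c("A_a", "A_w", "eps", "sigma", "tau", "mu"))
    expect_equal(fit$params[[nm]], s[[nm]], tolerance = 1e-6,
                 label = paste("recovered", nm))
})

test_that("area-table fitting tolerates 1% multiplicative noise", {
  s <- open_structure()
  errs <- sapply(1:20, function(seed) {
    tab <- generate_area_table(s, theta = seq(0.05, 0.95, length.out = 20),
                               noise = noise_model(sd = 0.01, seed = seed))
    fit <- fit_area_table(tab, seed = seed)
    nm <- c("A_a", "A_w", "sigma", "tau", "mu")
    abs(unlist(fit$params[nm]) - unlist(s[nm])) / unlist(s[nm])
  })
  expect_true(all(apply(errs, 1, median) < 0.05))
})

test_that("degenerate area tables are rejected", {
  expect_error(fit_area_table(data.frame(theta = 0.5, awa = 1, aws = 1)),
               ">= 6 rows")
  tab <- data.frame(theta = seq(0.1, 0.6, 0.1), awa = 0, aws = 1)
  expect_error(fit_area_table(tab), "positive")
  bad <- data.frame(theta = c(0.1, 0.1, 0.2, 0.3, 0.4, 0.5),
                    awa = 1, aws = 1)
  expect_error(validate_area_table(bad), "increasing")
})
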