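test_that("film closed form equals the closure with equal areas", {
  f <- solve_film(L = 0.8, alpha = 2, D = 0.5, k_wall = 0.7, Ceq = 1.3)
  expect_equal(f$Co, 1.3 / (1 + 0.7 * 0.8 / 0.5 + 0.7 / 2))
  expect_equal(f$flux, 0.7 * f$Co)
  expect_equal(solve_film(1, 1, 1, 0, 2)$Co, 2) # no uptake
  expect_equal(solve_film(1, 1, 1, 1, 3)$Co, 1) # unit groups: Ceq/3
  # identity with steady_concentrations at A_ws = A_wa, random draws
  set.seed(11)
  for (i in 1:50) {
    L <- exp(runif(1, -2, 2)); al <- exp(runif(1, -2, 2))
    D <- exp(runif(1, -2, 1)); kw <- exp(runif(1, -3, 2))
    Ceq <- exp(runif(1, -1, 1))
    f <- solve_film(L, al, D, kw, Ceq)
    sc <- steady_concentrations(kw, al, D, L, 1, 1, Ceq)
    expect_equal(f$Co, sc$Co, tolerance = 1e-14)
    expect_equal(f$c0, sc$c0, tolerance = 1e-14)
  }
})

test_that("grid solver reproduces the film to machine precision", {
  op <- oracle_pars()
  mask <- read_geometry(geometry_file("film"))
  n <- sum(mask == ".")
  p <- grid_problem(mask, h = op$h, D = op$D, alpha = 2, Ceq = 1,
                    k_wall = 0.7)
  g <- solve_grid(p)
  f <- solve_film(L = n * op$h, alpha = 2, D = op$D, k_wall = 0.7, Ceq = 1)
  expect_equal(g$Co_bar, f$Co, tolerance = 1e-12)
  expect_equal(g$c0_bar, f$c0, tolerance = 1e-12)
  expect_equal(g$L_bar, n * op$h) # hydraulic distance = film thickness
  # maximum principle
  expect_true(all(g$field[!is.na(g$field)] >= 0 &
                    g$field[!is.na(g$field)] <= 1))
})

test_that("uniform zero uptake yields a uniform saturated field", {
  p <- grid_problem(read_geometry(geometry_file("square")), h = 0.1, D = 1,
                    alpha = 5, Ceq = 2, k_wall = 0)
  g <- solve_grid(p)
  expect_equal(max(abs(g$field[!is.na(g$field)] - 2)), 0, tolerance = 1e-12)
  expect_equal(g$total_uptake, 0)
})

test_that("solver conserves mass and converges at second order in 2-D", {
  op <- oracle_pars()
  m0 <- read_geometry(geometry_file("square"))
  uptakes <- sapply(c(1, 2, 4, 8), function(r) {
    p <- grid_problem(refine_mask(m0, r), h = op$h / r, D = op$D,
                      alpha = op$alpha, Ceq = op$Ceq, k_wall = op$k_wall)
    g <- solve_grid(p)
    expect_lt(g$conservation_gap, 1e-10)
    g$total_uptake
  })
  # Richardson self-convergence: successive differences shrink ~4x
  d <- abs(diff(uptakes))
  order1 <- log2(d[1] / d[2]); order2 <- log2(d[2] / d[3])
  expect_gt(order1, 1.5); expect_lt(order1, 2.5)
  expect_gt(order2, 1.5); expect_lt(order2, 2.5)
})

test_that("closure error is small on compact fixtures, larger under contrast", {
  op <- oracle_pars()
  errs <- sapply(c("film", "square", "lshape", "patchy"), function(fx) {
    p <- grid_problem(read_geometry(geometry_file(fx)), h = op$h, D = op$D,
                      alpha = op$alpha, Ceq = op$Ceq, k_wall = op$k_wall)
    closure_error(p)$error
  })
  expect_lt(abs(errs[["film"]]), 1e-3) # exact up to discretization
  expect_lt(abs(errs[["square"]]), 0.2)
  expect_lt(abs(errs[["lshape"]]), 0.2)
  expect_lt(abs(errs[["patchy"]]), 0.2)

  # patchy bottom wall (interface on top, no-flux sides): alternating
  # k and 0 takes up less O2 than a uniform wall with the same mean,
  # because local uptake is concave in the local coefficient
  mk_bottom <- function(kpat) {
    m <- read_geometry(c("#IIIIIIIIIIII#", rep("#............#", 12),
                         "#WWWWWWWWWWWW#"))
    km <- matrix(0, nrow(m), ncol(m))
    wall <- which(m == "W")
    km[wall] <- rep_len(kpat, length(wall))
    grid_problem(m, h = op$h, D = op$D, alpha = op$alpha, Ceq = op$Ceq,
                 k_wall = km)
  }
  expect_lt(solve_grid(mk_bottom(c(1, 0)))$total_uptake,
            solve_grid(mk_bottom(0.5))$total_uptake)
  # 10x wall contrast: closure (which only sees the mean coefficient)
  # errs more than over the uniform wall
  expect_gt(abs(closure_error(mk_bottom(c(10, 1) / 11))$error),
            abs(closure_error(mk_bottom(0.5))$error))
})

test_that("masks are validated", {
  expect_error(read_geometry(c("#I#", "#x#")), "invalid mask")
  expect_error(read_geometry(c("#I#", "#.##")), "equal width")
  # two disconnected water pockets
  expect_error(grid_problem(c("#I#I#", "#.#.#", "#W#W#"), 0.1, 1, 1, 1, 1),
               "connected")
  # no interface anywhere
  expect_error(grid_problem(c("#W#", "#.#", "#W#"), 0.1, 1, 1, 1, 1),
               "interface")
})
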