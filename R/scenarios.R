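#' Temperature attenuation ratio of the feedback factor
#'
#' `Er'(Theta, T) = E_r(Theta, T) / E_r(Theta, T_base)`: how much more
#' strongly O2 dissolution-diffusion attenuates respiration at temperature
#' `T` than at the baseline (default 5 degC). Equals 1 at the baseline and
#' falls below 1 as warming raises demand faster than transport; the drop
#' steepens with saturation and with activation energy.
#'
#' @param model a [respiration_model()].
#' @param Theta saturation in (0, 1\].
#' @param T temperatures, degC (vectorized), `>= T_base`.
#' @param T_base baseline temperature, degC.
#' @return `Er'` values in (0, 1\] for `Ea > 0`.
#' @export
attenuation_ratio <- function(model, Theta, T, T_base = 5) {
  stopifnot(inherits(model, "respiration_model"))
  if (any(T < T_base)) .stopf("attenuation ratios are defined for T >= T_base")
  er <- function(Tc) evaluate_model(model, Theta, Tc)$Er
  vapply(T, er, numeric(1)) / er(T_base)
}

#' Moisture function: normalized respiration versus saturation
#'
#' The model's analogue of the empirical moisture functions used in soil
#' organic carbon models: respiration across a saturation grid at fixed
#' temperature, normalized by its maximum.
#'
#' @param model a [respiration_model()].
#' @param T temperature, degC.
#' @param Theta_grid saturation grid (>= 101 points for a stable maximum).
#' @return data frame with `Theta`, `omega`, `omega_norm` (max exactly 1).
#' @export
moisture_function <- function(model, T,
                              Theta_grid = seq(0, 1, length.out = 201)) {
  if (length(Theta_grid) < 101)
    .stopf("Theta_grid needs >= 101 points, got %d", length(Theta_grid))
  out <- evaluate_model(model, Theta_grid, T, normalize = TRUE)
  out[, c("Theta", "omega", "omega_norm")]
}

#' Optimal saturation for respiration at a given temperature
#'
#' Grid argmax (step `dtheta`) refined by golden-section search inside the
#' bracketing cell. Ties resolve to the smallest saturation; an optimum on
#' the grid boundary is flagged rather than silently returned.
#'
#' @param model a [respiration_model()].
#' @param T temperature, degC.
#' @param dtheta grid step.
#' @param tol golden-section half-width tolerance on Theta.
#' @return list with `theta_opt`, `omega_opt` and `boundary` flag.
#' @export
optimal_saturation <- function(model, T, dtheta = 0.01, tol = 1e-4) {
  grid <- seq(dtheta, 1, by = dtheta)
  om <- evaluate_model(model, grid, T)$omega
  i <- which.max(om) # first max: smallest Theta on ties
  boundary <- i == 1L || i == length(grid)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  f <- function(th) evaluate_model(model, th, T)$omega
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) { # keep left on ties -> smaller Theta
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  th <- (a + b) / 2
  list(theta_opt = th, omega_opt = f(th), boundary = boundary)
}

#' Effect of an open soil surface on the moisture response
#'
#' Evaluates the respiration-saturation curve for a family of
#' open-surface parameters. With `eps = 0` respiration vanishes at full
#' saturation (no interfacial area is left for O2 to dissolve through);
#' with `eps > 0` the soil surface keeps a fraction of pores in contact
#' with the atmosphere and respiration stays positive, increasingly so for
#' larger `eps`.
#'
#' @param model a [respiration_model()].
#' @param eps_list open-surface parameters, each in \[0, 0.2\].
#' @param T temperature, degC.
#' @param Theta_grid saturation grid.
#' @return long data frame with columns `eps`, `Theta`, `omega`.
#' @export
open_surface_study <- function(model, eps_list, T,
                               Theta_grid = seq(0, 1, length.out = 201)) {
  if (any(eps_list < 0 | eps_list > 0.2))
    .stopf("eps values must lie in [0, 0.2]")
  do.call(rbind, lapply(eps_list, function(e) {
    m <- update_model(model, eps = e)
    out <- evaluate_model(m, Theta_grid, T)
    data.frame(eps = e, Theta = out$Theta, omega = out$omega)
  }))
}
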