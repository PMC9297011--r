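#' Soil-architecture parameters for area-saturation relationships
#'
#' Bundles the parameters of the saturation parametrization of the water-air
#' interfacial area and wetted pore-wall area per unit soil volume,
#' \deqn{A_{wa}(\Theta) = A_a (1+\varepsilon-\Theta)^\sigma \Theta^\tau,
#'       \qquad A_{ws}(\Theta) = A_w \Theta^\mu,}
#' plus the hydraulic-distance scale \eqn{\lambda} of
#' \eqn{L = \lambda A_{ws}/A_{wa}}.
#'
#' @param A_a interfacial-area scale per unit sample volume (length-1, > 0).
#' @param A_w wetted-wall area scale per unit volume (length-1, > 0).
#' @param eps open-surface parameter in \[0, 1\]: a soil surface open to the
#'   atmosphere retains non-zero interfacial area at full saturation.
#' @param sigma,tau,mu dimensionless shape exponents in (0, 10\].
#' @param lam hydraulic-distance scale (length, > 0).
#' @return object of class `structure_params`.
#' @export
structure_params <- function(A_a, A_w, eps = 0, sigma = 1, tau = 1, mu = 2,
                             lam = 1) {
  for (nm in c("A_a", "A_w", "eps", "sigma", "tau", "mu", "lam"))
    .check_finite(get(nm), nm)
  if (A_a <= 0 || A_w <= 0) .stopf("A_a and A_w must be > 0")
  if (eps < 0 || eps > 1) .stopf("eps must lie in [0, 1], got %g", eps)
  for (nm in c("sigma", "tau", "mu")) {
    v <- get(nm)
    if (v <= 0 || v > 10) .stopf("%s must lie in (0, 10], got %g", nm, v)
  }
  if (lam <= 0) .stopf("lam must be > 0, got %g", lam)
  structure(list(A_a = A_a, A_w = A_w, eps = eps, sigma = sigma, tau = tau,
                 mu = mu, lam = lam),
            class = "structure_params")
}

#' @export
print.structure_params <- function(x, ...) {
  cat("Soil structure parameters:\n")
  cat(sprintf("  A_a = %g, A_w = %g (per unit volume), eps = %g\n",
              x$A_a, x$A_w, x$eps))
  cat(sprintf("  sigma = %g, tau = %g, mu = %g, lambda = %g\n",
              x$sigma, x$tau, x$mu, x$lam))
  invisible(x)
}

.check_theta <- function(Theta) {
  .check_finite(Theta, "Theta")
  if (any(Theta < 0 | Theta > 1))
    .stopf("saturation Theta must lie in [0, 1], got %g",
           Theta[which(Theta < 0 | Theta > 1)[1]])
  invisible(Theta)
}

#' Water-air interfacial and wetted pore-wall areas at a given saturation
#'
#' @param Theta saturation in \[0, 1\] (fraction of pore volume filled with
#'   water). Vectorized.
#' @param params a [structure_params()] object.
#' @return list with components `A_wa` (water-air interfacial area per unit
#'   volume, unimodal in Theta) and `A_ws` (wetted pore-wall area per unit
#'   volume, monotone increasing).
#' @export
interfacial_areas <- function(Theta, params) {
  stopifnot(inherits(params, "structure_params"))
  .check_theta(Theta)
  list(A_wa = params$A_a * (1 + params$eps - Theta)^params$sigma *
         Theta^params$tau,
       A_ws = params$A_w * Theta^params$mu)
}

#' Average hydraulic distance from water-air interfaces to reactive sites
#'
#' \eqn{L = \lambda A_{ws}/A_{wa}}: the mean within-water path length that
#' dissolved O2 travels from the interfaces where it dissolves to the
#' wetted pore walls hosting aerobic microbes; grows with saturation as
#' interfaces shrink relative to wetted walls.
#'
#' Where the interfacial area vanishes while wetted walls persist (a closed
#' soil at full saturation), `Inf` is returned as an "infinite resistance"
#' sentinel; downstream the feedback factor then collapses to 0.
#'
#' @inheritParams interfacial_areas
#' @return hydraulic distance (length units of `lam`); `Inf` sentinel when
#'   `A_wa == 0` with `A_ws > 0`; `NaN`-free.
#' @export
hydraulic_distance <- function(Theta, params) {
  a <- interfacial_areas(Theta, params)
  L <- params$lam * a$A_ws / a$A_wa
  # 0/0 at Theta = 0: no water, no path; define L = 0 there (unused anyway).
  L[a$A_ws == 0 & a$A_wa == 0] <- 0
  L
}

#' Fit the area-saturation parametrization to an area table
#'
#' Estimates (`A_w`, `mu`) by ordinary linear regression of `log(A_ws)` on
#' `log(Theta)`, and (`A_a`, `eps`, `sigma`, `tau`) by bounded nonlinear
#' least squares on `log(A_wa)` (multiplicative residuals: areas span orders
#' of magnitude across saturations) with seeded multistart. The
#' hydraulic-distance scale `lambda` never enters the area equations and is
#' deliberately not estimated here.
#'
#' @param table data frame with columns `theta`, `awa`, `aws` (areas per
#'   unit sample volume); at least 6 rows, `theta` strictly increasing.
#' @param n_starts number of multistart draws for the nonlinear fit.
#' @param seed integer seed for the multistart draws.
#' @return list with `params` (a [structure_params()] with `lam = 1`
#'   placeholder), `converged` flag, `objective` (SSE of log residuals) and
#'   `residuals` per row.
#' @export
fit_area_table <- function(table, n_starts = 5, seed = 1) {
  table <- validate_area_table(table)
  pos <- table$theta > 0 & table$awa > 0 & table$aws > 0
  if (sum(pos) < 6) .stopf("need >= 6 rows with positive theta and areas for the log-space fit")
  tb <- table[pos, ]

  ws_fit <- stats::lm(log(aws) ~ log(theta), data = tb)
  A_w <- exp(coef(ws_fit)[[1]])
  mu <- coef(ws_fit)[[2]]

  resid_fun <- function(p) {
    log(p[["A_a"]]) + p[["sigma"]] * log(1 + p[["eps"]] - tb$theta) +
      p[["tau"]] * log(tb$theta) - log(tb$awa)
  }
  lower <- c(A_a = 1e-8, eps = 0, sigma = 0.05, tau = 0.05)
  upper <- c(A_a = max(tb$awa) * 1e4, eps = 0.2, sigma = 10, tau = 10)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- c(A_a = exp(runif(1, log(max(tb$awa) / 10), log(max(tb$awa) * 10))),
               eps = runif(1, 0, 0.2),
               sigma = exp(runif(1, log(0.2), log(5))),
               tau = exp(runif(1, log(0.2), log(5))))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(list(params = NULL, converged = FALSE, objective = NA_real_,
                residuals = NULL))
  p <- best$par
  params <- structure_params(A_a = p[["A_a"]], A_w = A_w,
                             eps = p[["eps"]], sigma = p[["sigma"]],
                             tau = p[["tau"]], mu = min(max(mu, 1e-6), 10),
                             lam = 1)
  list(params = params,
       converged = best$info %in% 1:4,
       objective = best$deviance + sum(stats::residuals(ws_fit)^2),
       residuals = stats::residuals(best))
}

#' Validate an area-saturation table
#'
#' @param table data frame with columns `theta`, `awa`, `aws`.
#' @return the table, invisibly validated (theta strictly increasing in
#'   \[0,1\], areas non-negative, >= 6 rows).
#' @export
validate_area_table <- function(table) {
  if (!is.data.frame(table) || !all(c("theta", "awa", "aws") %in% names(table)))
    .stopf("area table must be a data frame with columns theta, awa, aws")
  if (nrow(table) < 6) .stopf("area table needs >= 6 rows, got %d", nrow(table))
  .check_theta(table$theta)
  if (any(diff(table$theta) <= 0)) .stopf("theta must be strictly increasing")
  if (any(table$awa < 0) || any(table$aws < 0)) .stopf("areas must be >= 0")
  table
}
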