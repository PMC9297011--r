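#' Validate a respiration dataset
#'
#' @param ds data frame with columns `theta` (\[0, 1\]), `T` (degC),
#'   `rate` (>= 0) and optionally `rep`.
#' @return the validated data frame.
#' @export
validate_respiration_dataset <- function(ds) {
  if (!is.data.frame(ds) || !all(c("theta", "T", "rate") %in% names(ds)))
    .stopf("respiration dataset must have columns theta, T, rate")
  .check_theta(ds$theta)
  .check_finite(ds$T, "T")
  .check_finite(ds$rate, "rate")
  if (any(ds$rate < 0)) .stopf("rates must be >= 0")
  ds
}

#' Normalize respiration rates by their maximum
#'
#' Divides every rate by the dataset maximum (the respiration at the
#' optimal water content), the convention under which moisture-response
#' curves are compared.
#'
#' @inheritParams validate_respiration_dataset
#' @return dataset with an added `rate_norm` column (`max(rate_norm) == 1`).
#' @export
normalize_rates <- function(ds) {
  ds <- validate_respiration_dataset(ds)
  m <- max(ds$rate)
  if (m <= 0) .stopf("cannot normalize: all rates are zero")
  ds$rate_norm <- ds$rate / m
  ds
}

# Parameter names, bounds and multistart scales of the identifiable set.
FIT_PARAMS <- c("mu", "tau", "sigma", "eps", "A", "psi_ref", "gamma", "scale")

.default_bounds <- list(
  mu = c(0.05, 10), tau = c(0.05, 10), sigma = c(0.05, 10),
  eps = c(0, 0.2), A = c(0.01, 100), psi_ref = c(1e-4, 1e4),
  gamma = c(0, 50), scale = c(0.2, 5))

.log_scaled <- c("mu", "tau", "sigma", "A", "psi_ref", "scale")

#' Specify which parameters a moisture-response fit should estimate
#'
#' @param free character vector of free parameters, a subset of
#'   `mu, tau, sigma, eps, A, psi_ref, gamma, scale`. `psi_ref` is the
#'   dimensionless demand-diffusion group at the fit temperature and `A`
#'   the area-scale ratio (see [model_from_groups()]); `scale` is a level
#'   factor between the model-normalized and data-normalized curves.
#' @param fixed named list of values for the parameters held fixed.
#' @param bounds named list of `c(lower, upper)` overriding the defaults.
#' @param n_starts number of seeded multistart draws.
#' @param seed integer seed.
#' @param dialect O2-physics dialect.
#' @param regime transfer regime (informational; fits use the
#'   diffusion-limited closed form).
#' @param loss `"linear"` (sum of squared differences of normalized
#'   rates, the conventional objective) or `"log"` (squared differences
#'   of log rates, the maximum-likelihood objective under multiplicative
#'   lognormal measurement noise; weights dry-end points where the area
#'   exponents act and is markedly more robust for such data).
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("mu", "tau", "sigma", "psi_ref", "scale"),
                     fixed = list(), bounds = list(), n_starts = 10,
                     seed = 1, dialect = "standard",
                     regime = "diffusion_limited", loss = "linear") {
  if (!loss %in% c("linear", "log")) .stopf("loss must be 'linear' or 'log'")
  if (!all(free %in% FIT_PARAMS))
    .stopf("unknown free parameters: %s",
           paste(setdiff(free, FIT_PARAMS), collapse = ", "))
  if (any(free %in% names(fixed)))
    .stopf("parameters cannot be both free and fixed")
  b <- modifyList(.default_bounds, bounds)
  structure(list(free = free, fixed = fixed, bounds = b,
                 n_starts = n_starts, seed = seed, dialect = dialect,
                 regime = regime, loss = loss),
            class = "fit_spec")
}

# Assemble the full group-parameter list from free values + spec fixed +
# defaults (eps = 0, A = 1, gamma = 0, scale = 1).
.full_pars <- function(free_vals, spec, Ea = 48000, T_ref = 15) {
  defaults <- list(mu = 2, tau = 1, sigma = 1, eps = 0, A = 1, psi_ref = 1,
                   gamma = 0, scale = 1)
  p <- modifyList(defaults, spec$fixed)
  p <- modifyList(p, as.list(free_vals))
  p$Ea <- Ea; p$T_ref <- T_ref; p$dialect <- spec$dialect
  p
}

# Model moisture curve normalized by its own maximum over a dense grid.
.model_norm_curve <- function(theta_eval, p) {
  grid <- sort(unique(c(seq(0.005, 1, by = 0.005), theta_eval)))
  om <- .omega_groups(grid, p$T_ref, p)
  m <- max(om)
  if (!is.finite(m) || m <= 0) return(rep(NA_real_, length(theta_eval)))
  .omega_groups(theta_eval, p$T_ref, p) / m
}

#' Fit the moisture response of respiration at a fixed temperature
#'
#' Minimizes the sum of squared differences between the data-normalized
#' rates and the model-normalized moisture curve over the free parameters,
#' using bounded Levenberg-Marquardt least squares with seeded multistart
#' (best of `n_starts` returned). The model curve is normalized by its own
#' maximum, with an explicit `scale` factor absorbing the level mismatch
#' with the data-normalized rates.
#'
#' @param ds respiration dataset at a single temperature (all rows within
#'   0.5 degC); needs at least 6 distinct saturations.
#' @param spec a [fit_spec()].
#' @return object of class `fit_result`: `estimates` (named vector over
#'   the free parameters), `pars` (full group-parameter list), `objective`
#'   (SSE on normalized rates), `residuals`, `converged`, `seed`,
#'   `n_starts`, `T_ref` (the data temperature).
#' @export
fit_moisture_response <- function(ds, spec = fit_spec()) {
  ds <- normalize_rates(ds)
  stopifnot(inherits(spec, "fit_spec"))
  if (diff(range(ds$T)) > 0.5)
    .stopf("moisture fit expects a single temperature (rows span %g degC)",
           diff(range(ds$T)))
  n_theta <- length(unique(ds$theta))
  if (n_theta < 6) .stopf("need >= 6 distinct saturations, got %d", n_theta)
  if (length(spec$free) > n_theta - 1)
    .stopf("under-determined fit: %d free parameters but only %d distinct saturations",
           length(spec$free), n_theta)
  T_ref <- mean(ds$T)

  # optimize log-scaled parameters in log space: better conditioned and
  # keeps multiplicative parameters positive
  to_internal <- function(v)
    ifelse(spec$free %in% .log_scaled, log(v), v)
  from_internal <- function(u)
    setNames(ifelse(spec$free %in% .log_scaled, exp(u), u), spec$free)
  use_log <- identical(spec$loss, "log")
  if (use_log && any(ds$rate_norm <= 0))
    .stopf("log loss requires strictly positive rates")
  resid_fun <- function(u) {
    v <- from_internal(u)
    p <- .full_pars(as.list(v), spec, T_ref = T_ref)
    mn <- .model_norm_curve(ds$theta, p)
    if (any(!is.finite(mn)) || (use_log && any(mn <= 0)))
      return(rep(1e6, nrow(ds)))
    if (use_log) log(p$scale * mn) - log(ds$rate_norm)
    else p$scale * mn - ds$rate_norm
  }
  lower <- to_internal(vapply(spec$bounds[spec$free], `[`, numeric(1), 1))
  upper <- to_internal(vapply(spec$bounds[spec$free], `[`, numeric(1), 2))
  set.seed(spec$seed)
  best <- NULL
  for (i in seq_len(spec$n_starts)) {
    start <- to_internal(vapply(spec$free, function(nm) {
      b <- spec$bounds[[nm]]
      if (nm %in% .log_scaled) exp(runif(1, log(b[1]), log(b[2])))
      else runif(1, b[1], b[2])
    }, numeric(1)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-14, ptol = 1e-14,
                           gtol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(estimates = NULL, pars = NULL,
                          objective = NA_real_, residuals = NULL,
                          converged = FALSE, seed = spec$seed,
                          n_starts = spec$n_starts, T_ref = T_ref,
                          spec = spec),
                     class = "fit_result"))
  est <- from_internal(as.numeric(best$par))
  structure(list(estimates = est,
                 pars = .full_pars(as.list(est), spec, T_ref = T_ref),
                 objective = best$deviance,
                 residuals = as.numeric(best$fvec),
                 converged = best$info %in% 1:4,
                 seed = spec$seed, n_starts = spec$n_starts,
                 T_ref = T_ref, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Moisture-response fit", if (isTRUE(x$converged)) "(converged)"
      else "(NOT converged)", "\n")
  if (!is.null(x$estimates)) {
    print(round(x$estimates, 5))
    cat(sprintf("  SSE = %.3g at T_ref = %g degC (%d starts, seed %d)\n",
                x$objective, x$T_ref, x$n_starts, x$seed))
  }
  invisible(x)
}

#' Predict the temperature response from a calibrated moisture fit
#'
#' Propagates the calibrated structure and demand groups across
#' temperature: demand follows the Arrhenius factor with intrinsic
#' activation energy `Ea`, the demand-diffusion group follows
#' `psi(T) = psi_ref * arrhenius_factor(Ea, T_ref, T) * D(T_ref)/D(T)`,
#' and O2 availability follows the dialect's Henry's-law curve. The curve
#' shape is the prediction; the level carries a single free scalar.
#'
#' @param fit a converged [fit_moisture_response()] result (or its `pars`
#'   list).
#' @param Ea intrinsic activation energy, J mol-1.
#' @param T_grid temperatures, degC, within the dialect validity range.
#' @param Theta_fixed saturation at which the response is evaluated.
#' @param dialect optional dialect override.
#' @return data frame with columns `T`, `omega` (relative units) and
#'   `omega_rel` (normalized to the first grid temperature).
#' @export
predict_temperature_response <- function(fit, Ea, T_grid, Theta_fixed = 0.6,
                                         dialect = NULL) {
  p <- if (inherits(fit, "fit_result")) {
    if (!isTRUE(fit$converged)) .stopf("fit did not converge")
    fit$pars
  } else fit
  p$Ea <- Ea
  if (!is.null(dialect)) p$dialect <- dialect
  om <- .omega_groups(rep(Theta_fixed, length(T_grid)), T_grid, p)
  data.frame(T = T_grid, omega = om, omega_rel = om / om[1])
}

#' Estimate the intrinsic activation energy from a temperature gradient
#'
#' With structure and demand groups fixed from a moisture fit, the only
#' unknown shaping the normalized temperature response is the intrinsic
#' `Ea`. This performs a 1-D bounded least-squares fit of the
#' max-normalized model curve to the max-normalized rates.
#'
#' @param ds respiration dataset with >= 3 distinct temperatures at a
#'   common saturation (all `theta` equal within 0.01).
#' @param fit a converged [fit_moisture_response()] result or `pars` list.
#' @param bounds `c(lower, upper)` for Ea, J mol-1.
#' @param dialect optional dialect override.
#' @return list with `Ea` (J mol-1), `objective`, `at_boundary` flag
#'   (estimate within 1% of a bound, e.g. for temperature-flat data) and
#'   `scale` (data max, the level matched out by normalization).
#' @export
fit_intrinsic_Ea <- function(ds, fit, bounds = c(5e3, 2e5),
                             dialect = NULL) {
  ds <- normalize_rates(ds)
  if (length(unique(ds$T)) < 3)
    .stopf("need >= 3 distinct temperatures, got %d", length(unique(ds$T)))
  if (diff(range(ds$theta)) > 0.01)
    .stopf("temperature fit expects a common saturation (theta spans %g)",
           diff(range(ds$theta)))
  p <- if (inherits(fit, "fit_result")) {
    if (!isTRUE(fit$converged)) .stopf("fit did not converge")
    fit$pars
  } else fit
  if (!is.null(dialect)) p$dialect <- dialect
  Theta <- mean(ds$theta)

  sse <- function(Ea) {
    p$Ea <- Ea
    om <- .omega_groups(rep(Theta, nrow(ds)), ds$T, p)
    m <- max(om)
    if (!is.finite(m) || m <= 0) return(1e12)
    sum((om / m - ds$rate_norm)^2)
  }
  # SSE(Ea) need not be unimodal (demand and transport effects can trade
  # off): bracket the global minimum on a grid, then refine locally
  grid <- seq(bounds[1], bounds[2], length.out = 81)
  i <- which.min(vapply(grid, sse, numeric(1)))
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(sse, interval = c(lo, hi), tol = 1)
  if (sse(grid[i]) < opt$objective)
    opt <- list(minimum = grid[i], objective = sse(grid[i]))
  span <- diff(bounds)
  list(Ea = opt$minimum, objective = opt$objective,
       at_boundary = opt$minimum < bounds[1] + 0.01 * span ||
         opt$minimum > bounds[2] - 0.01 * span,
       scale = max(ds$rate))
}

#' Apparent (bulk) activation energy by naive Arrhenius regression
#'
#' Ordinary least-squares regression of `log(rate)` on `-1/(R (T + 273))`,
#' the analysis a bulk respiration-temperature dataset is usually given.
#' Because O2 solubility falls and transport resistance grows with warming,
#' this apparent value underestimates the intrinsic activation energy of
#' the underlying kinetics.
#'
#' @param T temperatures, degC.
#' @param rate respiration rates (> 0).
#' @return apparent activation energy, J mol-1.
#' @export
apparent_Ea <- function(T, rate) {
  .check_finite(T, "T"); .check_finite(rate, "rate")
  if (any(rate <= 0)) .stopf("rates must be > 0 for Arrhenius regression")
  x <- -1 / (R_GAS * .kelvin(T))
  unname(coef(lm(log(rate) ~ x))[2])
}
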