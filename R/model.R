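#' Bundle structure, demand and transfer parameters into one model object
#'
#' @param s a [structure_params()].
#' @param d a [demand_params()].
#' @param t a [transfer_params()].
#' @param dialect O2-physics dialect (see [saturated_o2()]).
#' @param T_ref reference temperature, degC, at which demand groups are
#'   quoted.
#' @return object of class `respiration_model`.
#' @export
respiration_model <- function(s, d, t = transfer_params(),
                              dialect = "standard", T_ref = 15) {
  stopifnot(inherits(s, "structure_params"), inherits(d, "demand_params"),
            inherits(t, "transfer_params"))
  .check_dialect(dialect)
  structure(list(s = s, d = d, t = t, dialect = dialect, T_ref = T_ref),
            class = "respiration_model")
}

#' Build a model from its identifiable dimensionless groups
#'
#' Normalized respiration data identify only the area exponents, the area
#' ratio `A = A_a/A_w`, and the demand-diffusion group
#' `psi_ref = 2 k(T_ref) lambda / D(T_ref)`; the raw `k`, `lambda`, `A_a`,
#' `A_w` are not separately identifiable. This constructor realizes one
#' concrete member of the equivalence class (`A_w = 1`, `lambda = 1`,
#' `A_a = A`, `k` back-solved from `psi_ref`), which reproduces every
#' normalized prediction of the class.
#'
#' @param mu,tau,sigma area-saturation shape exponents.
#' @param eps open-surface parameter.
#' @param A area-scale ratio `A_a / A_w` (> 0).
#' @param psi_ref dimensionless demand-diffusion group
#'   `2 k(T_ref) lambda / D(T_ref)` (>= 0).
#' @param gamma saturation slope of demand (>= 0).
#' @param Ea intrinsic activation energy, J mol-1.
#' @param T_ref reference temperature, degC.
#' @param dialect O2-physics dialect.
#' @param regime transfer regime; `alpha_ratio` fixes `k(T_ref)/alpha` for
#'   non-diffusion-limited regimes.
#' @param alpha_ratio ratio `k(T_ref)/alpha` (default 1e-3: dissolution
#'   much faster than demand).
#' @return a [respiration_model()].
#' @export
model_from_groups <- function(mu, tau, sigma, eps = 0, A = 1, psi_ref = 1,
                              gamma = 0, Ea = 48000, T_ref = 15,
                              dialect = "standard",
                              regime = "diffusion_limited",
                              alpha_ratio = 1e-3) {
  if (A <= 0) .stopf("A must be > 0")
  if (psi_ref < 0) .stopf("psi_ref must be >= 0")
  D_ref <- o2_diffusivity(T_ref, dialect)
  k_ref <- psi_ref * D_ref / 2 # with lambda = 1
  s <- structure_params(A_a = A, A_w = 1, eps = eps, sigma = sigma,
                        tau = tau, mu = mu, lam = 1)
  d <- demand_from_reference(k_ref = k_ref, T_ref = T_ref, Ea = Ea,
                             gamma = gamma)
  t <- if (regime == "diffusion_limited") transfer_params()
       else transfer_params(alpha = if (k_ref > 0) k_ref / alpha_ratio else 1,
                            regime = regime)
  respiration_model(s, d, t, dialect = dialect, T_ref = T_ref)
}

#' Update selected components of a model
#'
#' @param model a [respiration_model()].
#' @param ... named structure fields (`A_a`, `A_w`, `eps`, `sigma`, `tau`,
#'   `mu`, `lam`), demand fields (`Ea`, `gamma`, ...) or `dialect`.
#' @return updated [respiration_model()].
#' @export
update_model <- function(model, ...) {
  stopifnot(inherits(model, "respiration_model"))
  upd <- list(...)
  s_f <- intersect(names(upd), names(model$s))
  d_f <- intersect(names(upd), names(model$d))
  s <- do.call(structure_params, modifyList(unclass(model$s), upd[s_f]))
  d <- do.call(demand_params, modifyList(unclass(model$d), upd[d_f]))
  dialect <- if ("dialect" %in% names(upd)) upd$dialect else model$dialect
  T_ref <- if ("T_ref" %in% names(upd)) upd$T_ref else model$T_ref
  respiration_model(s, d, model$t, dialect = dialect, T_ref = T_ref)
}

#' Evaluate the model over saturations and/or temperatures
#'
#' @param model a [respiration_model()].
#' @param Theta saturations in \[0, 1\] (vectorized).
#' @param T temperatures, degC (scalar or same length as `Theta`).
#' @param normalize normalize rates by the maximum over the evaluation?
#' @return `core_output` data frame (see [respiration_rate()]).
#' @export
evaluate_model <- function(model, Theta, T, normalize = FALSE) {
  stopifnot(inherits(model, "respiration_model"))
  respiration_curve(Theta, T, model$s, model$d, model$t,
                    dialect = model$dialect, normalize = normalize)
}

#' @export
print.respiration_model <- function(x, ...) {
  cat(sprintf("Respiration model ('%s' O2 physics, %s regime, T_ref = %g degC)\n",
              x$dialect, x$t$regime, x$T_ref))
  print(x$s)
  cat(sprintf("  Ea = %g J/mol, gamma = %g\n", x$d$Ea, x$d$gamma))
  invisible(x)
}

# Fast closed-form evaluator on the dimensionless groups; algebraically
# identical to evaluate_model() on model_from_groups() (tested), used in
# fitting loops. Returns rates relative to k(T_ref)*A_w*Ceq(T_ref).
.omega_groups <- function(Theta, T, p) {
  arr <- arrhenius_factor(p$Ea, p$T_ref, T)
  psi_T <- p$psi_ref * arr * o2_diffusivity(p$T_ref, p$dialect) /
    o2_diffusivity(T, p$dialect)
  B <- Theta^(p$mu - p$tau) * (1 + p$eps - Theta)^(-p$sigma)
  g <- B / (p$A * (1 + p$A / B))
  g[B == 0] <- 0
  het <- 1 + p$gamma * Theta
  Er <- 1 / (1 + psi_T * het * g)
  omega <- het * Theta^p$mu *
    (saturated_o2(T, p$dialect) / saturated_o2(p$T_ref, p$dialect)) * arr * Er
  omega[Theta == 0] <- 0
  omega
}
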