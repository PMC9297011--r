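#' Microbial potential oxygen demand parameters
#'
#' The lumped velocity \eqn{k} describing the maximal O2 uptake of aerobic
#' microbes per unit wetted pore-wall area when O2 is unlimited:
#' \deqn{k = n'(1-\beta)\, v\, e^{-E_a/(R(T+273))}\, \kappa\,
#'       \frac{C_D}{k_D + C_D},}
#' combining microbe areal density, the respired (non-assimilated) carbon
#' fraction, Arrhenius kinetics and Michaelis-Menten saturation in dissolved
#' organic carbon. An optional slope `gamma` lets demand grow linearly with
#' saturation, representing microbes and substrates being denser in the
#' larger pores that fill last.
#'
#' @param n_prime aerobic-microbe areal density on wetted walls
#'   (count length-2).
#' @param beta assimilated (growth) fraction of substrate uptake, in
#'   \[0, 1); `1 - beta` is respired.
#' @param kappa first-order O2 affinity coefficient (whole-community
#'   linearization of the Michaelis-Menten O2 term).
#' @param v Arrhenius pre-exponential (same units as the maximal uptake
#'   velocity).
#' @param Ea intrinsic activation energy, J mol-1.
#' @param C_D mean dissolved-organic-carbon concentration at wetted walls.
#' @param k_D DOC half-saturation constant (> 0).
#' @param gamma saturation slope of demand (>= 0); demand is multiplied by
#'   `1 + gamma * Theta` when a saturation is supplied.
#' @return object of class `demand_params`.
#' @export
demand_params <- function(n_prime = 1, beta = 0.3, kappa = 1, v = 1,
                          Ea = 48000, C_D = 1, k_D = 1, gamma = 0) {
  for (nm in c("n_prime", "beta", "kappa", "v", "Ea", "C_D", "k_D", "gamma"))
    .check_finite(get(nm), nm)
  if (any(c(n_prime, kappa, v, Ea, C_D, gamma) < 0))
    .stopf("demand parameters must be non-negative")
  if (beta < 0 || beta >= 1) .stopf("beta must lie in [0, 1), got %g", beta)
  if (k_D <= 0) .stopf("k_D must be > 0, got %g", k_D)
  structure(list(n_prime = n_prime, beta = beta, kappa = kappa, v = v,
                 Ea = Ea, C_D = C_D, k_D = k_D, gamma = gamma),
            class = "demand_params")
}

#' Demand parameters from a reference-temperature demand value
#'
#' Convenience constructor: given the lumped demand `k_ref` calibrated at
#' `T_ref` (typically 15 degC), back-solves the Arrhenius pre-exponential so
#' that `potential_demand(d, T_ref)` equals `k_ref` exactly. The individual
#' constituents (microbe density, carbon-use efficiency, DOC level) are not
#' identifiable from respiration data and are fixed at neutral values.
#'
#' @param k_ref lumped demand velocity at the reference temperature (>= 0).
#' @param T_ref reference temperature, degC.
#' @inheritParams demand_params
#' @return a [demand_params()] object.
#' @export
demand_from_reference <- function(k_ref, T_ref = 15, Ea = 48000, gamma = 0) {
  .check_finite(k_ref, "k_ref")
  if (k_ref < 0) .stopf("k_ref must be >= 0")
  # n' (1-beta) kappa C_D/(k_D+C_D) = 1 * 1 * 1 * 0.5 with the defaults below
  v <- 2 * k_ref / exp(-Ea / (R_GAS * .kelvin(T_ref)))
  demand_params(n_prime = 1, beta = 0, kappa = 1, v = v, Ea = Ea,
                C_D = 1, k_D = 1, gamma = gamma)
}

#' Potential microbial O2 demand per unit wetted-wall area
#'
#' @param d a [demand_params()] object.
#' @param T temperature, degC.
#' @param Theta optional saturation in \[0, 1\]; when supplied, demand is
#'   multiplied by `1 + gamma * Theta`.
#' @return lumped demand velocity `k` (>= 0); linear in `n_prime`,
#'   saturating in `C_D`, Arrhenius in `T`.
#' @export
potential_demand <- function(d, T, Theta = NULL) {
  stopifnot(inherits(d, "demand_params"))
  .check_finite(T, "T")
  k <- d$n_prime * (1 - d$beta) * d$v * exp(-d$Ea / (R_GAS * .kelvin(T))) *
    d$kappa * d$C_D / (d$k_D + d$C_D)
  if (!is.null(Theta)) {
    .check_theta(Theta)
    k <- k * (1 + d$gamma * Theta)
  }
  k
}

O2_REGIMES <- c("diffusion_limited", "general", "dissolution_limited")

#' Oxygen transfer parameters
#'
#' @param alpha first-order dissolution rate coefficient at the water-air
#'   interface (velocity); must be > 0 unless `regime = "diffusion_limited"`
#'   (where dissolution is treated as instantaneous and `alpha` is ignored).
#' @param regime `"diffusion_limited"` (default: dissolution much faster
#'   than aqueous diffusion, the regime all headline analyses use),
#'   `"general"` (both resistances), or `"dissolution_limited"`.
#' @return object of class `transfer_params`.
#' @export
transfer_params <- function(alpha = Inf, regime = "diffusion_limited") {
  if (!regime %in% O2_REGIMES)
    .stopf("`regime` must be one of: %s", paste(O2_REGIMES, collapse = ", "))
  if (regime != "diffusion_limited") {
    .check_finite(alpha, "alpha")
    if (alpha <= 0) .stopf("alpha must be > 0 for regime '%s'", regime)
  }
  structure(list(alpha = alpha, regime = regime), class = "transfer_params")
}

#' Steady-state interface and wall O2 concentrations and diffusive flux
#'
#' Solves the quasi-steady O2 budget of the volumetric-average closure: the
#' mass dissolved at water-air interfaces equals the mass diffusing through
#' water equals the mass respired at wetted walls,
#' \deqn{\alpha A_{wa}(C_{eq} - c_0) = D\frac{c_0 - C_o}{L}
#'       \frac{A_{ws}+A_{wa}}{2} = k A_{ws} C_o.}
#' All arguments are vectorized.
#'
#' @param k potential demand velocity (>= 0).
#' @param alpha dissolution rate coefficient (> 0; `Inf` allowed).
#' @param D aqueous O2 diffusivity.
#' @param L hydraulic distance (`Inf` sentinel allowed).
#' @param A_wa,A_ws interfacial and wetted-wall areas per unit volume
#'   (not both zero).
#' @param Ceq saturated dissolved O2 concentration.
#' @return list with `c0` (interface concentration), `Co` (mean wall
#'   concentration) and `Q` (diffusive flux per unit soil volume), obeying
#'   `0 <= Co <= c0 <= Ceq`.
#' @export
steady_concentrations <- function(k, alpha, D, L, A_wa, A_ws, Ceq) {
  n <- max(lengths(list(k, alpha, D, L, A_wa, A_ws, Ceq)))
  k <- rep_len(k, n); alpha <- rep_len(alpha, n); D <- rep_len(D, n)
  L <- rep_len(L, n); A_wa <- rep_len(A_wa, n); A_ws <- rep_len(A_ws, n)
  Ceq <- rep_len(Ceq, n)
  if (any(c(k, D, A_wa, A_ws, Ceq) < 0) || any(alpha <= 0) || any(L < 0))
    .stopf("steady_concentrations: arguments must be non-negative (alpha > 0)")
  if (any(A_wa + A_ws == 0))
    .stopf("steady_concentrations: A_wa and A_ws cannot both be zero")

  Gd <- 2 * L * k * A_ws / (D * (A_ws + A_wa))   # diffusion resistance group
  Ga <- k * A_ws / (alpha * A_wa)                # dissolution resistance group
  # Infinite-resistance sentinel: no interface but active demand -> Co = 0.
  sent <- (A_wa == 0 | is.infinite(L)) & k > 0
  Gd[sent] <- Inf; Ga[sent] <- 0
  # k = 0: no uptake, uniform saturation concentration.
  Gd[k == 0] <- 0; Ga[k == 0] <- 0

  Co <- Ceq / (1 + Gd + Ga)
  c0 <- Co * (1 + Gd)
  c0[sent] <- Ceq # no dissolution flux, interface (if any) at equilibrium
  Q <- k * A_ws * Co
  list(c0 = c0, Co = Co, Q = Q)
}

#' Feedback factor attenuating potential respiration
#'
#' The multiplicative factor \eqn{E_r \in (0, 1]} that emerges from the
#' volumetric average: the ratio of realized respiration to the potential
#' rate \eqn{k A_{ws} C_{eq}}, set by the resistances to O2 dissolution and
#' aqueous diffusion,
#' \deqn{E_r = \left[1 + \frac{k}{\alpha}\left(
#'   \frac{2\alpha L}{D}\frac{A_{ws}}{A_{ws}+A_{wa}} +
#'   \frac{A_{ws}}{A_{wa}}\right)\right]^{-1}.}
#' `regime = "diffusion_limited"` drops the dissolution term (alpha
#' infinite); `"dissolution_limited"` drops the diffusion term.
#'
#' @inheritParams steady_concentrations
#' @param regime one of `"general"`, `"diffusion_limited"`,
#'   `"dissolution_limited"`.
#' @return `E_r` in \[0, 1\]; 1 when `k = 0`; 0 at the infinite-resistance
#'   sentinel (`A_wa = 0` with `k > 0`).
#' @export
feedback_factor <- function(k, alpha = Inf, D, L, A_wa, A_ws,
                            regime = "general") {
  if (!regime %in% O2_REGIMES)
    .stopf("`regime` must be one of: %s", paste(O2_REGIMES, collapse = ", "))
  n <- max(lengths(list(k, alpha, D, L, A_wa, A_ws)))
  k <- rep_len(k, n); alpha <- rep_len(alpha, n); D <- rep_len(D, n)
  L <- rep_len(L, n); A_wa <- rep_len(A_wa, n); A_ws <- rep_len(A_ws, n)
  Gd <- 2 * L * k * A_ws / (D * (A_ws + A_wa))
  Ga <- k * A_ws / (alpha * A_wa)
  if (regime == "diffusion_limited") Ga <- 0
  if (regime == "dissolution_limited") Gd <- 0
  sent <- (A_wa == 0 | is.infinite(L)) & k > 0
  G <- Gd + Ga
  G[sent] <- Inf
  G[k == 0] <- 0
  G[k > 0 & A_ws == 0] <- 0 # no reactive sites: nothing to attenuate
  1 / (1 + G)
}

#' Respiration rate at a given saturation and temperature
#'
#' Assembles the full closed-form model
#' \eqn{\Omega(\Theta, T) = k\, A_{ws}\, C_{eq}\, E_r}: potential demand
#' times wetted-wall area times Henry's-law O2 availability, attenuated by
#' the emergent dissolution-diffusion feedback factor. With
#' `regime = "diffusion_limited"` this is identical to the printed
#' closed-form expression combining the area parametrization with the
#' diffusion-limited feedback factor.
#'
#' @param Theta saturation in \[0, 1\].
#' @param T temperature, degC (within the dialect validity range).
#' @param s a [structure_params()].
#' @param d a [demand_params()].
#' @param t a [transfer_params()] (default diffusion-limited).
#' @param dialect O2-physics dialect, see [saturated_o2()].
#' @return one-row data frame of class `core_output` with columns `Theta`,
#'   `T`, `A_wa`, `A_ws`, `L`, `k`, `Ceq`, `D`, `c0`, `Co`, `Q`, `Er`,
#'   `omega`, `dialect`.
#' @export
respiration_rate <- function(Theta, T, s, d, t = transfer_params(),
                             dialect = "standard") {
  stopifnot(inherits(s, "structure_params"), inherits(d, "demand_params"),
            inherits(t, "transfer_params"))
  .check_theta(Theta)
  a <- interfacial_areas(Theta, s)
  L <- hydraulic_distance(Theta, s)
  k <- potential_demand(d, T, Theta)
  Ceq <- saturated_o2(T, dialect)
  D <- o2_diffusivity(T, dialect)
  n <- length(Theta)
  alpha <- if (is.infinite(t$alpha)) 1e30 else t$alpha
  Er <- feedback_factor(k, t$alpha, D, L, a$A_wa, a$A_ws, regime = t$regime)
  omega <- k * a$A_ws * rep_len(Ceq, n) * Er

  # concentrations consistent with the selected regime
  if (t$regime == "general") {
    sc <- steady_concentrations(k, alpha, D, L, a$A_wa, a$A_ws, Ceq)
  } else if (t$regime == "diffusion_limited") {
    Co <- rep_len(Ceq, n) * Er
    sc <- list(c0 = rep_len(Ceq, n), Co = Co, Q = k * a$A_ws * Co)
  } else { # dissolution_limited: no aqueous gradient
    Co <- rep_len(Ceq, n) * Er
    sc <- list(c0 = Co, Co = Co, Q = k * a$A_ws * Co)
  }
  out <- data.frame(Theta = Theta, T = rep_len(T, n), A_wa = a$A_wa,
                    A_ws = a$A_ws, L = L, k = k, Ceq = rep_len(Ceq, n),
                    D = rep_len(D, n), c0 = sc$c0, Co = sc$Co, Q = sc$Q,
                    Er = Er, omega = omega,
                    dialect = dialect, row.names = NULL)
  class(out) <- c("core_output", class(out))
  out
}

#' Respiration rate across a saturation grid
#'
#' @param Theta_grid non-empty numeric vector of saturations in \[0, 1\].
#' @inheritParams respiration_rate
#' @param normalize if `TRUE`, adds a column `omega_norm` dividing rates by
#'   the curve maximum (so the maximum is exactly 1), mirroring the
#'   convention of normalizing respiration by its value at the optimal
#'   water content.
#' @return `core_output` data frame with one row per grid point.
#' @export
respiration_curve <- function(Theta_grid, T, s, d, t = transfer_params(),
                              dialect = "standard", normalize = FALSE) {
  if (length(Theta_grid) == 0) .stopf("Theta_grid must be non-empty")
  out <- respiration_rate(Theta_grid, T, s, d, t, dialect)
  if (normalize) {
    m <- max(out$omega)
    if (m <= 0) .stopf("cannot normalize an all-zero respiration curve")
    out$omega_norm <- out$omega / m
  }
  out
}
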