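#' Arrhenius temperature factor for microbial metabolic rate
#'
#' Ratio of a first-order kinetic coefficient at temperature `T` to its value
#' at a reference temperature, \eqn{\exp[(E_a/R)(1/T_{ref,K} - 1/T_K)]},
#' with temperatures converted to Kelvin by the model's additive offset of
#' 273. Used to propagate the potential microbial O2 demand calibrated at a
#' reference temperature (typically 15 degC) to other temperatures.
#'
#' @param Ea activation energy, J mol-1 (>= 0).
#' @param T_ref reference temperature, degC.
#' @param T target temperature, degC. Vectorized.
#' @return dimensionless ratio k(T)/k(T_ref); 1 when `T == T_ref`, strictly
#'   increasing in `T` for `Ea > 0`.
#' @examples
#' arrhenius_factor(48000, 15, 25) # about 1.96, a Q10-like doubling
#' @export
arrhenius_factor <- function(Ea, T_ref, T) {
  .check_finite(Ea, "Ea"); .check_finite(T_ref, "T_ref"); .check_finite(T, "T")
  if (Ea < 0) .stopf("activation energy `Ea` must be >= 0, got %g", Ea)
  if (T_ref <= -KELVIN_OFFSET || any(T <= -KELVIN_OFFSET))
    .stopf("temperatures must exceed absolute zero (%g degC)", -KELVIN_OFFSET)
  exp((Ea / R_GAS) * (1 / .kelvin(T_ref) - 1 / .kelvin(T)))
}

# The two oxygen-physics dialects.
#
# `as_printed` evaluates the source correlations verbatim (outputs in
# arbitrary "model units", meaningful only in ratios). Its diffusivity
# decreases with temperature, which is unphysical for O2 in water; it is
# retained for traceability.
#
# `standard` uses the Benson & Krause (1984) O2 solubility correlation
# (mg L-1 at 1 atm moist air; USGS DOTABLES form) and a diffusivity
# correlation of the same exponential form but with quadratic term
# -(506.4/(T+273))^2, which makes diffusivity increase with temperature as
# it must.
O2_DIALECTS <- c("standard", "as_printed")

.check_dialect <- function(dialect) {
  if (!is.character(dialect) || length(dialect) != 1L ||
      !dialect %in% O2_DIALECTS)
    .stopf("`dialect` must be one of: %s", paste(O2_DIALECTS, collapse = ", "))
  dialect
}

# Validity range shared by both dialects; covers all scenarios of interest
# (2-35 degC) with margin. Outside it we refuse rather than extrapolate.
O2_T_RANGE <- c(0, 45)

.check_o2_temperature <- function(T, dialect) {
  .check_finite(T, "T")
  if (any(T < O2_T_RANGE[1] | T > O2_T_RANGE[2]))
    .stopf("temperature %g degC outside the [%g, %g] degC validity range of the '%s' O2-physics dialect",
           T[which(T < O2_T_RANGE[1] | T > O2_T_RANGE[2])[1]],
           O2_T_RANGE[1], O2_T_RANGE[2], dialect)
  invisible(T)
}

#' Saturated dissolved-oxygen concentration at the water-air interface
#'
#' Henry's-law equilibrium concentration of dissolved O2 at 1 atm as a
#' function of temperature. Two dialects are provided because the model's
#' printed correlation is internally inconsistent with the physical
#' behaviour it describes: `"as_printed"` evaluates
#' \eqn{C_{eq} = 0.434\exp(0.000064T^2 - 0.0114T + 1.161)} verbatim
#' (model units, use in ratios only); `"standard"` (default) evaluates the
#' Benson-Krause correlation in mg L-1, which falls from about 12.8 mg L-1
#' at 5 degC to 6.9 mg L-1 at 35 degC.
#'
#' @param T temperature, degC, within \[0, 45\]. Vectorized.
#' @param dialect `"standard"` or `"as_printed"`.
#' @return saturated concentration, strictly decreasing in `T`.
#' @export
saturated_o2 <- function(T, dialect = "standard") {
  .check_dialect(dialect)
  .check_o2_temperature(T, dialect)
  if (dialect == "as_printed") {
    0.434 * exp(0.000064 * T^2 - 0.0114 * T + 1.161)
  } else {
    TK <- T + 273.15 # published correlation is written against 273.15
    exp(-139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
          1.2438e10 / TK^3 - 8.621949e11 / TK^4)
  }
}

#' Molecular diffusion coefficient of dissolved oxygen in water
#'
#' `"as_printed"` evaluates
#' \eqn{D = 0.434\exp[-4.41 + 773.8/(T+273) - 2564.4/(T+273)^2]} verbatim;
#' note these constants make D decrease with temperature. `"standard"`
#' (default) replaces the quadratic term by \eqn{-(506.4/(T+273))^2} so that
#' diffusivity increases with temperature, matching the physics the model
#' relies on (warming enhances aqueous O2 diffusion).
#'
#' @inheritParams saturated_o2
#' @return diffusion coefficient in model units.
#' @export
o2_diffusivity <- function(T, dialect = "standard") {
  .check_dialect(dialect)
  .check_o2_temperature(T, dialect)
  TK <- .kelvin(T)
  if (dialect == "as_printed") {
    0.434 * exp(-4.41 + 773.8 / TK - 2564.4 / TK^2)
  } else {
    0.434 * exp(-4.41 + 773.8 / TK - (506.4 / TK)^2)
  }
}
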