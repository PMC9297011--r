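#' Noise model for synthetic datasets
#'
#' @param kind `"multiplicative_lognormal"` (default: respiration rates
#'   are positive and heteroscedastic, so noise scales with the signal) or
#'   `"additive_gaussian"`.
#' @param sd noise standard deviation (log-scale sd for the lognormal
#'   kind; roughly the coefficient of variation for small `sd`).
#' @param seed integer seed (mandatory: every synthetic table is
#'   reproducible).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = "multiplicative_lognormal", sd = 0.02, seed) {
  if (missing(seed)) .stopf("a seed is mandatory for noise models")
  kinds <- c("multiplicative_lognormal", "additive_gaussian")
  if (!kind %in% kinds)
    .stopf("`kind` must be one of: %s", paste(kinds, collapse = ", "))
  .check_finite(sd, "sd")
  if (sd < 0) .stopf("sd must be >= 0")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

.apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  set.seed(noise$seed)
  if (noise$sd == 0) return(x)
  if (noise$kind == "multiplicative_lognormal")
    x * exp(rnorm(length(x), 0, noise$sd))
  else x + rnorm(length(x), 0, noise$sd)
}

#' Reference ground-truth model for simulation studies
#'
#' The package's default soil: area exponents `mu = 3`, `tau = 1`,
#' `sigma = 1`, closed surface (`eps = 0`), equal area scales (`A = 1`),
#' demand-diffusion group `psi_ref = 0.8` at 15 degC, intrinsic
#' `Ea = 48` kJ mol-1, standard O2 physics. Chosen so the optimal
#' saturation falls from roughly 0.76 at 2 degC to 0.63 at 30 degC,
#' bracketing the ~60% saturation conventionally used as optimal in
#' incubation studies.
#'
#' @param ... overrides passed to [model_from_groups()].
#' @return a [respiration_model()].
#' @export
default_ground_truth <- function(...) {
  args <- modifyList(list(mu = 3, tau = 1, sigma = 1, eps = 0, A = 1,
                          psi_ref = 0.8, gamma = 0, Ea = 48000, T_ref = 15,
                          dialect = "standard"),
                     list(...))
  do.call(model_from_groups, args)
}

#' Ground-truth model for parameter-recovery simulation studies
#'
#' A soil in which the O2 dissolution-diffusion feedback is clearly active
#' over the sampled saturation range (`psi_ref = 3`, so the feedback factor
#' falls well below 1): `mu = 2`, `tau = 1`, `sigma = 1.5`. Recovery
#' studies are run at this point because the area exponents only shape the
#' respiration curve where the feedback acts; in a weakly O2-limited soil
#' they are close to unidentifiable from normalized rates, and a
#' simulation study there would measure the soil, not the estimator.
#'
#' @param ... overrides passed to [model_from_groups()].
#' @return a [respiration_model()].
#' @export
recovery_ground_truth <- function(...) {
  default_ground_truth(mu = 2, tau = 1, sigma = 1.5, psi_ref = 3, ...)
}

#' Generate a synthetic respiration dataset from a known model
#'
#' Emulates the two incubation designs the model is calibrated against:
#' a saturation sweep at fixed temperature (default 15 saturations from
#' 0.07 to 0.8 at 15 degC, in triplicate) and, by passing a temperature
#' vector with a single saturation, a temperature sweep at fixed moisture
#' (e.g. 5-35 degC at 60% saturation).
#'
#' @param model a [respiration_model()] ground truth.
#' @param noise a [noise_model()].
#' @param theta saturations of the design.
#' @param T temperatures of the design, degC.
#' @param reps replicates per (theta, T) cell.
#' @return data frame `theta, T, rate, rep` with attributes
#'   `ground_truth` (the model) and `seed`; deterministic given the seed.
#' @export
generate_respiration_dataset <- function(model, noise,
                                         theta = seq(0.07, 0.8,
                                                     length.out = 15),
                                         T = 15, reps = 3) {
  stopifnot(inherits(model, "respiration_model"))
  design <- expand.grid(rep = seq_len(reps), theta = theta, T = T,
                        KEEP.OUT.ATTRS = FALSE)
  design <- design[, c("theta", "T", "rep")]
  mu <- evaluate_model(model, design$theta, design$T)$omega
  design$rate <- .apply_noise(mu, noise)
  attr(design, "ground_truth") <- model
  attr(design, "seed") <- noise$seed
  rownames(design) <- NULL
  design[, c("theta", "T", "rate", "rep")]
}

#' Generate a synthetic area-saturation table from known structure
#'
#' Evaluates the area parametrization on a saturation grid and applies
#' noise, emulating the area-saturation curves extracted from X-ray
#' imaged soil samples.
#'
#' @param s a [structure_params()] ground truth.
#' @param theta saturation grid (strictly increasing).
#' @param noise a [noise_model()].
#' @return data frame `theta, awa, aws` with attributes `ground_truth`
#'   and `seed`.
#' @export
generate_area_table <- function(s, theta = seq(0.05, 1, by = 0.05), noise) {
  stopifnot(inherits(s, "structure_params"))
  a <- interfacial_areas(theta, s)
  stopifnot(inherits(noise, "noise_model"))
  set.seed(noise$seed)
  vals <- c(a$A_wa, a$A_ws)
  if (noise$sd > 0) {
    if (noise$kind == "multiplicative_lognormal")
      vals <- vals * exp(rnorm(length(vals), 0, noise$sd))
    else vals <- pmax(vals + rnorm(length(vals), 0, noise$sd), 0)
  }
  out <- data.frame(theta = theta,
                    awa = vals[seq_along(theta)],
                    aws = vals[seq_along(theta) + length(theta)])
  attr(out, "ground_truth") <- s
  attr(out, "seed") <- noise$seed
  out
}
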