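# Shared fixtures for the test suite. Everything is built in code.

# a soil with a mildly open surface, used where eps > 0 matters
open_structure <- function() {
  structure_params(A_a = 2, A_w = 5, eps = 0.05, sigma = 1.4, tau = 0.8,
                   mu = 2.3, lam = 0.7)
}

closed_structure <- function() {
  structure_params(A_a = 1, A_w = 1, eps = 0, sigma = 1, tau = 1, mu = 2,
                   lam = 1)
}

# random valid draws of the closure inputs, used by property tests
draw_closure_inputs <- function(n, seed) {
  set.seed(seed)
  list(k = exp(runif(n, -3, 3)), alpha = exp(runif(n, -2, 4)),
       D = exp(runif(n, -3, 1)), L = exp(runif(n, -2, 2)),
       A_wa = exp(runif(n, -2, 2)), A_ws = exp(runif(n, -2, 2)),
       Ceq = exp(runif(n, -1, 1)))
}

# geometry fixture paths
geometry_file <- function(name) {
  system.file("extdata", "geometries", paste0(name, ".txt"),
              package = "oxyresp")
}

# oracle fixture transport parameters used across tests
oracle_pars <- function() list(h = 0.1, D = 1, alpha = 100, Ceq = 1,
                               k_wall = 0.5)

# direct transcription of the printed closed-form respiration model
# (diffusion-limited feedback composed with the area parametrization),
# kept independent of the package's composition path
omega_printed <- function(Theta, k, A_w, A, lam, D, Ceq, mu, tau, sigma,
                          eps) {
  Er <- 1 / (1 + 2 * k * lam * Theta^(mu - tau) * (1 + eps - Theta)^(-sigma) /
               (D * A + D * A^2 * Theta^(tau - mu) * (1 + eps - Theta)^sigma))
  k * A_w * Theta^mu * Ceq * Er
}
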