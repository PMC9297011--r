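#' Read a model parameter file (YAML or JSON)
#'
#' Recognized keys: `A_a, A_w, eps, sigma, tau, mu, lam` (soil
#' architecture), `k15` (lumped demand at 15 degC), `Ea`, `gamma`
#' (demand), `alpha`, `regime` (O2 transfer) and `dialect`. Missing keys
#' take the package defaults.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a [respiration_model()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) .stopf("parameter file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  model_from_config(cfg)
}

#' Build a model from a configuration list
#'
#' @param cfg named list with the keys of [read_model_file()].
#' @return a [respiration_model()].
#' @export
model_from_config <- function(cfg) {
  defaults <- list(A_a = 1, A_w = 1, eps = 0, sigma = 1, tau = 1, mu = 3,
                   lam = 1, k15 = 0.0014, Ea = 48000, gamma = 0,
                   alpha = Inf, regime = "diffusion_limited",
                   dialect = "standard")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    .stopf("unknown parameter keys: %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  s <- structure_params(A_a = cfg$A_a, A_w = cfg$A_w, eps = cfg$eps,
                        sigma = cfg$sigma, tau = cfg$tau, mu = cfg$mu,
                        lam = cfg$lam)
  d <- demand_from_reference(k_ref = cfg$k15, T_ref = 15, Ea = cfg$Ea,
                             gamma = cfg$gamma)
  t <- transfer_params(alpha = cfg$alpha, regime = cfg$regime)
  respiration_model(s, d, t, dialect = cfg$dialect, T_ref = 15)
}

# JSON with sorted keys, pretty-printed, for diffable outputs.
.write_json_sorted <- function(x, path) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v) > 0)
      lapply(v[order(names(v))], sort_rec)
    else v
  }
  jsonlite::write_json(sort_rec(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

.config_echo <- function(extra = list()) {
  c(list(package = "oxyresp",
         version = as.character(utils::packageVersion("oxyresp"))),
    extra)
}

.wb_usage <- paste(
  "usage: oxyresp <subcommand> [options]",
  "subcommands:",
  "  simulate  --what respiration|areas --out PREFIX [--params FILE]",
  "            [--seed N] [--sd X]",
  "  fit-areas --in CSV --out JSON [--seed N]",
  "  fit       --in CSV --out JSON [--free p1,p2,...] [--seed N]",
  "  predict   --fit JSON --out CSV [--Ea X] [--theta X]",
  "  scenario  --what attenuation|moisture|optimal|open-surface --out CSV",
  "            [--params FILE] [--T X]",
  "  oracle    --fixture film|square|lshape|patchy --out JSON",
  sep = "\n")

.wb_args <- function(argv) {
  # --key value pairs -> named list
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    if (!startsWith(argv[i], "--"))
      .stopf("expected --option, got '%s'\n%s", argv[i], .wb_usage)
    key <- sub("^--", "", argv[i])
    if (i == length(argv)) .stopf("option --%s needs a value", key)
    out[[key]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

.wb_get <- function(opts, key, default = NULL, numeric = FALSE) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (is.null(default)) .stopf("missing required option --%s\n%s", key, .wb_usage)
    v <- default
  }
  if (numeric) as.numeric(v) else v
}

#' Run the command-line workbench
#'
#' Thin dispatcher tying the modules into reproducible runs. Every output
#' embeds the echoed configuration, the seed and the package version;
#' re-running with the same configuration and seed reproduces identical
#' payloads. Results go to files; messages to stderr.
#'
#' @param argv character vector of command-line arguments
#'   (subcommand first), e.g. `c("simulate", "--what", "respiration",
#'   "--out", "run1", "--seed", "7")`.
#' @return exit status, invisibly (0 on success); errors raise conditions.
#' @export
run_workbench <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) .stopf("no subcommand given\n%s", .wb_usage)
  sub <- argv[1]
  opts <- .wb_args(argv[-1])
  model_of <- function() {
    if (!is.null(opts$params)) read_model_file(opts$params)
    else default_ground_truth()
  }

  if (sub == "simulate") {
    what <- .wb_get(opts, "what")
    seed <- as.integer(.wb_get(opts, "seed", "1"))
    sd <- .wb_get(opts, "sd", "0.02", numeric = TRUE)
    out <- .wb_get(opts, "out")
    noise <- noise_model(sd = sd, seed = seed)
    if (what == "respiration") {
      ds <- generate_respiration_dataset(model_of(), noise)
      write.csv(ds, paste0(out, ".csv"), row.names = FALSE)
      gt <- model_of()
      .write_json_sorted(.config_echo(list(
        seed = seed, sd = sd, what = what,
        ground_truth = c(unclass(gt$s),
                         list(Ea = gt$d$Ea, gamma = gt$d$gamma,
                              dialect = gt$dialect)))),
        paste0(out, ".json"))
    } else if (what == "areas") {
      s <- model_of()$s
      tab <- generate_area_table(s, noise = noise)
      write.csv(tab, paste0(out, ".csv"), row.names = FALSE)
      .write_json_sorted(.config_echo(list(
        seed = seed, sd = sd, what = what, ground_truth = unclass(s))),
        paste0(out, ".json"))
    } else .stopf("unknown simulate target '%s'\n%s", what, .wb_usage)
    message("simulate: wrote ", out, ".csv")

  } else if (sub == "fit-areas") {
    tab <- read.csv(.wb_get(opts, "in"))
    if (!all(c("theta", "awa", "aws") %in% names(tab)))
      .stopf("area CSV must have columns theta,awa,aws")
    seed <- as.integer(.wb_get(opts, "seed", "1"))
    fit <- fit_area_table(tab, seed = seed)
    .write_json_sorted(.config_echo(list(
      seed = seed, converged = fit$converged, objective = fit$objective,
      params = unclass(fit$params))), .wb_get(opts, "out"))
    message("fit-areas: converged = ", fit$converged)

  } else if (sub == "fit") {
    ds <- read.csv(.wb_get(opts, "in"))
    if (!all(c("theta", "T", "rate") %in% names(ds)))
      .stopf("respiration CSV must have columns theta,T,rate")
    seed <- as.integer(.wb_get(opts, "seed", "1"))
    free <- strsplit(.wb_get(opts, "free", "mu,tau,sigma,psi_ref"), ",")[[1]]
    fit <- fit_moisture_response(ds, fit_spec(free = free, seed = seed))
    .write_json_sorted(.config_echo(list(
      seed = seed, converged = fit$converged, objective = fit$objective,
      T_ref = fit$T_ref, estimates = as.list(fit$estimates),
      pars = fit$pars[FIT_PARAMS])), .wb_get(opts, "out"))
    message("fit: converged = ", fit$converged,
            ", SSE = ", signif(fit$objective, 4))

  } else if (sub == "predict") {
    fj <- jsonlite::read_json(.wb_get(opts, "fit"), simplifyVector = TRUE)
    pars <- c(fj$pars, list(Ea = .wb_get(opts, "Ea", "48000", numeric = TRUE),
                            T_ref = fj$T_ref, dialect = "standard"))
    T_grid <- seq(.wb_get(opts, "tmin", "5", numeric = TRUE),
                  .wb_get(opts, "tmax", "35", numeric = TRUE), by = 1)
    curve <- predict_temperature_response(
      pars, Ea = pars$Ea, T_grid = T_grid,
      Theta_fixed = .wb_get(opts, "theta", "0.6", numeric = TRUE))
    write.csv(curve, .wb_get(opts, "out"), row.names = FALSE)
    message("predict: wrote ", .wb_get(opts, "out"))

  } else if (sub == "scenario") {
    what <- .wb_get(opts, "what")
    model <- model_of()
    Tc <- .wb_get(opts, "T", "15", numeric = TRUE)
    out <- .wb_get(opts, "out")
    res <- switch(what,
      "attenuation" = {
        Tg <- seq(5, 35, by = 2.5)
        do.call(rbind, lapply(c(0.3, 0.5, 0.7, 0.9), function(th)
          data.frame(Theta = th, T = Tg,
                     Er_prime = attenuation_ratio(model, th, Tg))))
      },
      "moisture" = cbind(T = Tc, moisture_function(model, Tc)),
      "optimal" = {
        Tg <- seq(2, 30, by = 2)
        data.frame(T = Tg, theta_opt = vapply(Tg, function(Ti)
          optimal_saturation(model, Ti)$theta_opt, numeric(1)))
      },
      "open-surface" = cbind(T = Tc,
        open_surface_study(model, c(0, 0.01, 0.05), Tc)),
      .stopf("unknown scenario '%s'\n%s", what, .wb_usage))
    write.csv(res, out, row.names = FALSE)
    message("scenario ", what, ": wrote ", out)

  } else if (sub == "oracle") {
    fx <- .wb_get(opts, "fixture")
    path <- system.file("extdata", "geometries", paste0(fx, ".txt"),
                        package = "oxyresp")
    if (!nzchar(path)) .stopf("unknown fixture '%s'\n%s", fx, .wb_usage)
    p <- grid_problem(path, h = 0.1, D = 1, alpha = 100, Ceq = 1,
                      k_wall = 0.5)
    ce <- closure_error(p)
    .write_json_sorted(.config_echo(list(
      fixture = fx, closure_error = ce$error,
      conservation_gap = ce$grid$conservation_gap,
      c0_bar = ce$grid$c0_bar, Co_bar = ce$grid$Co_bar,
      total_uptake = ce$grid$total_uptake,
      L_bar = ce$grid$L_bar)), .wb_get(opts, "out"))
    message("oracle ", fx, ": closure error = ", signif(ce$error, 4))

  } else {
    .stopf("unknown subcommand '%s'\n%s", sub, .wb_usage)
  }
  invisible(0L)
}
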