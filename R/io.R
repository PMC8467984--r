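# Configuration files and pipeline runners.
#
# A run configuration is a YAML file with sections:
#   model:    case, a, b, c, f, s, and A (saturation) or B (competition)
#   noise:    two_D1/two_D2 (printed 2D_i convention) or D1/D2, lambda1,
#             lambda2, m1, m2
#   numerics: optional lvsa_control fields plus seed
#   compare:  optional; intensity, lambdas (for the L2 sweep)
#   simulate: optional; n_paths, t_end, burn_in, dt, record_stride
#   output:   optional; dir
# Unknown keys anywhere are rejected.

check_keys <- function(x, allowed, section) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("config section '%s': unknown key(s) %s", section,
                 paste(sQuote(extra), collapse = ", ")), call. = FALSE)
}

#' Read and validate a run configuration
#'
#' @param path YAML configuration file.
#' @return list with validated components `params` ([lv_params()]),
#'   `noise` ([lv_noise()]), `control` ([lvsa_control()]), `seed`, and
#'   the raw `compare`, `simulate`, `output` sections.
#' @export
read_lvsa_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("model", "noise", "numerics", "compare", "simulate",
                    "output"), "(top level)")
  if (is.null(cfg$model) || is.null(cfg$noise))
    stop("config must contain 'model' and 'noise' sections",
         call. = FALSE)
  check_keys(cfg$model, c("case", "a", "b", "c", "f", "s", "A", "B"),
             "model")
  m <- cfg$model
  params <- do.call(lv_params, m)
  check_keys(cfg$noise, c("D1", "D2", "two_D1", "two_D2", "lambda1",
                          "lambda2", "m1", "m2"), "noise")
  if (!is.null(cfg$noise$D1) && !is.null(cfg$noise$two_D1) ||
      !is.null(cfg$noise$D2) && !is.null(cfg$noise$two_D2))
    stop("noise section: keys D_i and two_D_i are mutually exclusive",
         call. = FALSE)
  noise <- do.call(lv_noise, cfg$noise)
  num <- cfg$numerics
  check_keys(num, c("n_levels", "n_dense", "r_max", "r_lo", "tail_tol",
                    "max_extend", "seed"), "numerics")
  seed <- num$seed
  num$seed <- NULL
  control <- do.call(lvsa_control, if (is.null(num)) list() else num)
  check_keys(cfg$compare, c("intensity", "lambdas", "two_D1", "two_D2"),
             "compare")
  check_keys(cfg$simulate, c("n_paths", "t_end", "burn_in", "dt",
                             "record_stride"), "simulate")
  check_keys(cfg$output, "dir", "output")
  list(params = params, noise = noise, control = control, seed = seed,
       compare = cfg$compare, simulate = cfg$simulate,
       output = cfg$output)
}

resolve_out_dir <- function(config, out_dir) {
  if (is.null(out_dir)) out_dir <- config$output$dir
  if (is.null(out_dir)) out_dir <- "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

#' Run the full stationary-solution pipeline from a configuration
#'
#' Fits the model and writes `orbit_table.csv`, `coefficients.csv`,
#' `stationary.csv`, `marginals.csv` and `moments.json` into the output
#' directory.
#'
#' @param config path to a YAML configuration or the result of
#'   [read_lvsa_config()].
#' @param out_dir output directory (default: the config's `output: dir`,
#'   else the working directory).
#' @param n_x marginal grid resolution.
#' @return invisibly, the [lvsa()] fit.
#' @export
run_solve <- function(config, out_dir = NULL, n_x = 400L) {
  if (is.character(config)) config <- read_lvsa_config(config)
  out_dir <- resolve_out_dir(config, out_dir)
  fit <- lvsa(config$params, config$noise, config$control)
  write_orbit_table(fit$table, file.path(out_dir, "orbit_table.csv"))
  write_coefficients(fit$coeffs, file.path(out_dir, "coefficients.csv"))
  write_stationary(fit$sol, file.path(out_dir, "stationary.csv"))
  rows <- list()
  for (ax in c("prey", "predator"))
    for (wh in c("perturbation", "gaussian")) {
      mp <- marginal_pdf(fit$sol, fit$table, ax, which = wh,
                         rel.tol = 1e-7)
      rows[[paste(ax, wh)]] <- data.frame(axis = ax, which = wh,
                                          x = mp$x,
                                          density = mp$density)
    }
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
                   file.path(out_dir, "marginals.csv"),
                   row.names = FALSE, quote = FALSE)
  mom <- list(perturbation = stationary_moments(fit$sol, fit$table,
                                                "perturbation"),
              gaussian = stationary_moments(fit$sol, fit$table,
                                            "gaussian"),
              kappa = fit$sol$kappa, tail_mass = fit$sol$tail_mass,
              neg_mass = fit$sol$neg_mass)
  jsonlite::write_json(mom, file.path(out_dir, "moments.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the constant-intensity L2 comparison sweep
#'
#' For each mean arrival rate, solves the stationary problem with jump
#' variance `intensity / lambda` and writes the L2 discrepancies of
#' both marginals to `l2_table.csv` (columns `lambda`, `m`, `l2_x1`,
#' `l2_x2`).
#'
#' @inheritParams run_solve
#' @param lambdas overrides the config's `compare: lambdas`.
#' @return invisibly, the sweep data frame.
#' @export
run_compare <- function(config, out_dir = NULL, lambdas = NULL) {
  if (is.character(config)) config <- read_lvsa_config(config)
  out_dir <- resolve_out_dir(config, out_dir)
  cmp <- config$compare
  if (is.null(cmp$intensity))
    stop("config lacks 'compare: intensity' (constant lambda*E[Y^2])",
         call. = FALSE)
  if (is.null(lambdas)) lambdas <- cmp$lambdas
  if (is.null(lambdas))
    stop("no lambda list given (config 'compare: lambdas' or argument)",
         call. = FALSE)
  two_D1 <- if (!is.null(cmp$two_D1)) cmp$two_D1 else 2 * config$noise$D1
  two_D2 <- if (!is.null(cmp$two_D2)) cmp$two_D2 else 2 * config$noise$D2
  tab <- lambda_sweep(config$params, lambdas, cmp$intensity,
                      two_D1 = two_D1, two_D2 = two_D2,
                      control = config$control)
  utils::write.csv(format(tab, digits = 17, trim = TRUE),
                   file.path(out_dir, "l2_table.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Run the Monte Carlo validation pipeline
#'
#' Simulates the jump-diffusion model and writes `samples.csv` (pooled
#' recorded states), `empirical_marginals.csv` and
#' `empirical_moments.json`.
#'
#' @inheritParams run_solve
#' @param seed overrides the config's `numerics: seed`.
#' @return invisibly, the `"lv_sim"` object.
#' @export
run_simulate <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_lvsa_config(config)
  out_dir <- resolve_out_dir(config, out_dir)
  sc <- config$simulate
  if (is.null(seed)) seed <- config$seed
  sim <- simulate_paths(config$params, config$noise,
                        n_paths = if (is.null(sc$n_paths)) 100L
                                  else sc$n_paths,
                        t_end = if (is.null(sc$t_end)) 2000 else sc$t_end,
                        burn_in = sc$burn_in, dt = sc$dt,
                        record_stride = if (is.null(sc$record_stride)) 10L
                                        else sc$record_stride,
                        seed = seed)
  n_rec <- ncol(sim$x1)
  df <- data.frame(t = rep(sim$times, each = nrow(sim$x1)),
                   path = rep(seq_len(nrow(sim$x1)), n_rec),
                   x1 = as.vector(sim$x1), x2 = as.vector(sim$x2))
  utils::write.csv(df, file.path(out_dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  rows <- lapply(c("prey", "predator"), function(ax) {
    ep <- empirical_pdf(sim, ax, min_samples = 1e3)
    data.frame(axis = ax, x = ep$x, density = ep$density)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "empirical_marginals.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(mc_moments(sim),
                       file.path(out_dir, "empirical_moments.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
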