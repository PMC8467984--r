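#' L2 discrepancy sweep over the Poisson mean arrival rate
#'
#' Reproduces the constant-intensity comparison between the second-order
#' perturbation marginals and the Gaussian approximation: for each
#' \eqn{\lambda} in `lambdas`, the jump-magnitude variance is set to
#' `intensity / lambda` (both channels), the stationary problem is
#' solved, and the L2 discrepancies of the prey and predator marginals
#' are computed. As \eqn{\lambda} grows at fixed intensity, Poisson
#' forcing approaches Gaussian forcing and both columns decrease.
#'
#' The orbit table is built once and shared by all \eqn{\lambda}: it
#' depends only on the deterministic skeleton.
#'
#' @param params an [lv_params()] object.
#' @param lambdas vector of mean arrival rates (> 0).
#' @param intensity constant Poisson intensity \eqn{\lambda E[Y^2]}.
#' @param two_D1,two_D2 Gaussian intensities \eqn{2D_i}.
#' @param control an [lvsa_control()].
#' @param n_x grid resolution of the squared-difference integrals.
#' @return data frame with columns `lambda`, `m` (jump variance),
#'   `l2_x1`, `l2_x2`.
#' @export
lambda_sweep <- function(params, lambdas, intensity,
                         two_D1 = 0.001, two_D2 = 0.001,
                         control = lvsa_control(), n_x = 400L) {
  stopifnot(inherits(params, "lv_params"), all(lambdas > 0),
            intensity > 0)
  eff <- effective_params(params)
  table <- NULL
  out <- data.frame(lambda = lambdas, m = intensity / lambdas,
                    l2_x1 = NA_real_, l2_x2 = NA_real_)
  for (i in seq_along(lambdas)) {
    noise <- lv_noise(two_D1 = two_D1, two_D2 = two_D2,
                      lambda1 = lambdas[i], lambda2 = lambdas[i],
                      m1 = out$m[i], m2 = out$m[i])
    if (is.null(table)) {
      fit <- lvsa(params, noise, control)
      table <- fit$table; coeffs <- fit$coeffs; sol <- fit$sol
    } else {
      coeffs <- coefficient_functions(eff, noise, table)
      sol <- assemble_stationary(coeffs, control$n_dense)
    }
    out$l2_x1[i] <- l2_perturbation_vs_gaussian(sol, table, "prey",
                                                n_x = n_x)
    out$l2_x2[i] <- l2_perturbation_vs_gaussian(sol, table, "predator",
                                                n_x = n_x)
  }
  out
}

#' Moment sweep over the saturation / competition coefficient
#'
#' Recomputes the stationary means and relative fluctuations of both
#' populations along a grid of the predator-saturation coefficient `A`
#' (saturation case) or predator-competition coefficient `B`
#' (competition case), at fixed noise.
#'
#' @param params an [lv_params()] object; its `A` (or `B`) field is
#'   replaced by each sweep value in turn.
#' @param values sweep values (>= 0).
#' @param noise an [lv_noise()] object.
#' @param control an [lvsa_control()].
#' @return data frame with the sweep value and the moment summary per
#'   row (perturbation solution).
#' @export
interaction_sweep <- function(params, values, noise,
                              control = lvsa_control()) {
  stopifnot(inherits(params, "lv_params"))
  rows <- lapply(values, function(v) {
    pv <- if (params$case == "saturation")
      lv_params("saturation", params$a, params$b, params$c, params$f,
                s = params$s, A = v)
    else
      lv_params("competition", params$a, params$b, params$c, params$f,
                s = params$s, B = v)
    fit <- lvsa(pv, noise, control)
    mom <- stationary_moments(fit$sol, fit$table, "perturbation")
    data.frame(value = v, mean_x1 = mom$mean_x1, mean_x2 = mom$mean_x2,
               var_x1 = mom$var_x1, var_x2 = mom$var_x2,
               relfluct_x1 = mom$relfluct_x1,
               relfluct_x2 = mom$relfluct_x2)
  })
  do.call(rbind, rows)
}
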