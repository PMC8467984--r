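#' Control settings for the stochastic-averaging solver
#'
#' @param n_levels orbit-table grid size (levels of the first integral).
#' @param n_dense dense evaluation grid size for the stationary solver.
#' @param r_max largest level; `NULL` selects it automatically so that
#'   the stationary tail mass beyond it is below `tail_tol`.
#' @param r_lo smallest tabulated level; `NULL` uses
#'   `1e-4 * a_bar * c`.
#' @param tail_tol stationary tail-mass tolerance driving `r_max`.
#' @param max_extend maximum number of automatic `r_max` enlargements.
#' @return list of class `"lvsa_control"`.
#' @export
lvsa_control <- function(n_levels = 101L, n_dense = 4001L, r_max = NULL,
                         r_lo = NULL, tail_tol = 1e-8, max_extend = 6L) {
  structure(list(n_levels = as.integer(n_levels),
                 n_dense = as.integer(n_dense),
                 r_max = r_max, r_lo = r_lo, tail_tol = tail_tol,
                 max_extend = as.integer(max_extend)),
            class = "lvsa_control")
}

#' Fit the stochastic-averaging model of a noisy predator-prey system
#'
#' The central entry point: takes one ecosystem ([lv_params()]) and one
#' noise setting ([lv_noise()]) and carries out the full analysis
#' pipeline — effective parameters, orbit table of the Lotka-Volterra
#' first integral, averaged generalized FPK coefficients, and the
#' stationary level density by the second-order perturbation scheme
#' (with its Gaussian approximation alongside).
#'
#' The largest tabulated level is enlarged automatically until the
#' stationary density's tail mass beyond it falls below
#' `control$tail_tol`.
#'
#' @param params an [lv_params()] object.
#' @param noise an [lv_noise()] object.
#' @param control an [lvsa_control()] object.
#' @return An object of class `"lvsa"` with components `params`, `noise`,
#'   `eff`, `table` (orbit table), `coeffs`, `sol` (stationary
#'   densities), `control`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' fit <- lvsa(lv_params("saturation", 1, 1, 0.5, 0.5, s = 0.1, A = 0.05),
#'             lv_noise(two_D1 = 0.001, two_D2 = 0.001,
#'                      lambda1 = 0.1, lambda2 = 0.1, m1 = 0.08, m2 = 0.08))
#' summary(fit)
#' }
#' @export
lvsa <- function(params, noise, control = lvsa_control()) {
  stopifnot(inherits(params, "lv_params"), inherits(noise, "lv_noise"),
            inherits(control, "lvsa_control"))
  eff <- effective_params(params)
  r_max <- control$r_max
  if (is.null(r_max)) {
    # initial guess from the leading dissipation/diffusion balance:
    # p0 ~ exp(-beta r) with beta ~ 2 (s/f_bar) <A11^2>' / A21bar'(0)
    Gam <- eff$c * (2 * noise$D1 + noise$lambda1 * noise$m1) +
      eff$a_bar * (2 * noise$D2 + noise$lambda2 * noise$m2)
    beta <- 2 * (params$s / eff$f_bar) * eff$c / max(Gam, 1e-300)
    r_max <- if (is.finite(beta) && beta > 0) 30 / beta
             else eff$a_bar * eff$c
  }
  table <- NULL; coeffs <- NULL; sol <- NULL
  for (k in seq_len(control$max_extend + 1L)) {
    table <- build_orbit_table(eff, r_max = r_max,
                               n_levels = control$n_levels,
                               r_lo = control$r_lo)
    coeffs <- coefficient_functions(eff, noise, table)
    p0sol <- solve_p0(coeffs, control$n_dense)
    if (p0sol$tail_mass <= control$tail_tol) break
    if (k > control$max_extend)
      stop(sprintf(paste0("stationary tail mass %.3g still above %.3g at ",
                          "r_max = %.3g: no normalizable stationary ",
                          "density in reach (is the self-competition ",
                          "coefficient s positive?)"),
                   p0sol$tail_mass, control$tail_tol, r_max),
           call. = FALSE)
    r_max <- r_max * 1.6
  }
  sol <- assemble_stationary(coeffs, control$n_dense)
  structure(list(params = params, noise = noise, eff = eff,
                 table = table, coeffs = coeffs, sol = sol,
                 control = control),
            class = "lvsa")
}

# allow observables to take a fitted object directly
resolve_sol <- function(sol, table) {
  if (inherits(sol, "lvsa")) list(sol = sol$sol, table = sol$table)
  else list(sol = sol, table = table)
}

#' @export
print.lvsa <- function(x, ...) {
  cat(sprintf("Stochastic-averaging fit: %s case\n", x$params$case))
  print(x$eff)
  print(x$noise)
  cat(sprintf("  stationary grid: r in [%.3g, %.3g], kappa = %.4g\n",
              x$sol$r[1], x$sol$r[length(x$sol$r)], x$sol$kappa))
  cat(sprintf("  max pG = %.5g, max pR = %.5g\n",
              max(x$sol$pG), max(x$sol$pR)))
  invisible(x)
}

#' @export
coef.lvsa <- function(object, ...) {
  c(a_bar = object$eff$a_bar, b_bar = object$eff$b_bar,
    f_bar = object$eff$f_bar, c = object$eff$c)
}

#' @export
summary.lvsa <- function(object, ...) {
  mp <- stationary_moments(object$sol, object$table, "perturbation")
  mg <- stationary_moments(object$sol, object$table, "gaussian")
  out <- list(fit = object, perturbation = mp, gaussian = mg)
  class(out) <- "summary.lvsa"
  out
}

#' @export
print.summary.lvsa <- function(x, ...) {
  print(x$fit)
  fmt <- function(m) sprintf(
    "    E[X1] = %.6g, E[X2] = %.6g\n    Var[X1] = %.6g, Var[X2] = %.6g\n    relative fluctuations: %.6g, %.6g\n",
    m$mean_x1, m$mean_x2, m$var_x1, m$var_x2,
    m$relfluct_x1, m$relfluct_x2)
  cat("  Second-order perturbation solution:\n", fmt(x$perturbation))
  cat("  Gaussian approximation:\n", fmt(x$gaussian))
  invisible(x)
}

#' Predict densities or first-integral levels at states
#'
#' @param object an [lvsa()] fit.
#' @param newdata data frame with columns `x1`, `x2`.
#' @param type `"joint"` (stationary joint density) or `"level"` (value
#'   of the first integral).
#' @param which solution variant for `type = "joint"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.lvsa <- function(object, newdata,
                         type = c("joint", "level"),
                         which = c("perturbation", "gaussian"), ...) {
  type <- match.arg(type)
  which <- match.arg(which)
  stopifnot(is.data.frame(newdata), all(c("x1", "x2") %in% names(newdata)))
  if (type == "level")
    return(first_integral(object$eff, newdata$x1, newdata$x2))
  joint_pdf(object$sol, object$table, newdata$x1, newdata$x2, which)
}

#' Plot marginal stationary PDFs of a fit
#'
#' Draws the second-order perturbation marginal and the Gaussian
#' approximation for one or both axes.
#'
#' @param x an [lvsa()] fit.
#' @param axis `"prey"`, `"predator"`, or `"both"`.
#' @param n_x grid resolution.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the list of computed marginals.
#' @export
plot.lvsa <- function(x, axis = c("both", "prey", "predator"),
                      n_x = 150L, ...) {
  axis <- match.arg(axis)
  axes <- if (axis == "both") c("prey", "predator") else axis
  old <- NULL
  if (length(axes) == 2L) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  out <- list()
  for (ax in axes) {
    r_cut <- level_mass_cut(x$sol)
    ext <- level_extents(x$eff, r_cut)
    xs <- if (ax == "prey")
      seq(ext[["x1_min"]], ext[["x1_max"]], length.out = n_x)
    else seq(ext[["x2_min"]], ext[["x2_max"]], length.out = n_x)
    mp <- marginal_pdf(x$sol, x$table, ax, xs, "perturbation",
                       rel.tol = 1e-6)
    mg <- marginal_pdf(x$sol, x$table, ax, xs, "gaussian",
                       rel.tol = 1e-6)
    graphics::matplot(xs, cbind(mp$density, mg$density), type = "l",
                      lty = c(1, 2), col = c("black", "grey40"),
                      xlab = if (ax == "prey") "prey density x1"
                             else "predator density x2",
                      ylab = "stationary PDF", ...)
    graphics::legend("topright", c("perturbation", "Gaussian approx."),
                     lty = c(1, 2), col = c("black", "grey40"),
                     bty = "n")
    out[[ax]] <- list(perturbation = mp, gaussian = mg)
  }
  invisible(out)
}
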