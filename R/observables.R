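#' Joint stationary PDF of the population densities
#'
#' Maps the stationary level density back to state space:
#' \deqn{p(x_1, x_2) = \frac{p_R(r(x_1, x_2))}{T(r(x_1, x_2))\, x_1 x_2}.}
#' The factor \eqn{1/(T x_1 x_2)} is the Jacobian of the change of
#' variables to (level, orbit-time): in log coordinates the unperturbed
#' flow is canonically Hamiltonian, so the probability carried by a level
#' band spreads uniformly in time along the orbit.
#'
#' @param sol an [assemble_stationary()] object.
#' @param table the [build_orbit_table()] the solution was built from.
#' @param x1,x2 strictly positive coordinates (vectorized).
#' @param which `"perturbation"`, `"gaussian"`, or `"difference"`
#'   (perturbation minus Gaussian).
#' @return density values.
#' @export
joint_pdf <- function(sol, table, x1, x2,
                      which = c("perturbation", "gaussian", "difference")) {
  rs <- resolve_sol(sol, table); sol <- rs$sol; table <- rs$table
  stopifnot(inherits(sol, "lv_stationary"), inherits(table, "orbit_table"))
  which <- match.arg(which)
  r <- first_integral(table$eff, x1, x2)
  pr <- switch(which,
               perturbation = stationary_density(sol, r, "perturbation"),
               gaussian = stationary_density(sol, r, "gaussian"),
               difference = stationary_density(sol, r, "perturbation") -
                 stationary_density(sol, r, "gaussian"))
  pr / (orbit_column(table, "T", r) * x1 * x2)
}

#' Level at which a stationary density reaches a cumulative-mass target
#'
#' Smallest tabulated level r with \eqn{\int_0^r p_R = } `mass`.
#' @param sol an [assemble_stationary()] object.
#' @param mass cumulative-mass target (default `1 - 1e-6`).
#' @return scalar level.
#' @export
level_mass_cut <- function(sol, mass = 1 - 1e-6) {
  if (inherits(sol, "lvsa")) sol <- sol$sol
  cum <- cumtrapz(sol$t, sol$pR * sol$r) + sol$pR[1] * sol$r[1] / sol$kappa
  i <- which(cum >= mass * cum[length(cum)])[1]
  sol$r[if (is.na(i)) length(sol$r) else i]
}

#' Marginal stationary PDF of one population density
#'
#' Integrates the joint PDF over the companion coordinate by adaptive
#' quadrature, for each requested grid point. Integration limits come
#' from the extent of the level curve at the cumulative-mass cutoff of
#' the stationary solution.
#'
#' @inheritParams joint_pdf
#' @param axis `"prey"` (x1) or `"predator"` (x2).
#' @param x evaluation grid (defaults to 400 points spanning the support
#'   at the mass cutoff).
#' @param r_cut support cutoff level (defaults to [level_mass_cut()]).
#' @param rel.tol quadrature tolerance per point.
#' @return An object of class `"lv_marginal"`: list with `axis`, `x`,
#'   `density`, `provenance`.
#' @export
marginal_pdf <- function(sol, table,
                         axis = c("prey", "predator"), x = NULL,
                         which = c("perturbation", "gaussian",
                                   "difference"),
                         r_cut = NULL, rel.tol = 1e-8) {
  rs <- resolve_sol(sol, table); sol <- rs$sol; table <- rs$table
  stopifnot(inherits(sol, "lv_stationary"), inherits(table, "orbit_table"))
  axis <- match.arg(axis)
  which <- match.arg(which)
  eff <- table$eff
  if (is.null(r_cut)) r_cut <- level_mass_cut(sol)
  ext <- level_extents(eff, r_cut)
  if (is.null(x)) {
    x <- if (axis == "prey")
      seq(ext[["x1_min"]], ext[["x1_max"]], length.out = 400L)
    else seq(ext[["x2_min"]], ext[["x2_max"]], length.out = 400L)
  }
  # own-coordinate potential and companion-coordinate geometry
  if (axis == "prey") {
    own_phi <- function(v) phi1(eff, v)
    comp_k <- eff$b_bar; comp_m <- eff$a_bar
    comp_star <- eff$x2_star
  } else {
    own_phi <- function(v) phi2(eff, v)
    comp_k <- eff$f_bar; comp_m <- eff$c
    comp_star <- eff$x1_star
  }
  dens <- vapply(x, function(xi) {
    rho <- own_phi(xi)
    if (rho >= r_cut) return(0)
    ylo <- phi_invert(comp_k, comp_m, r_cut - rho, lower = TRUE)
    yhi <- phi_invert(comp_k, comp_m, r_cut - rho, lower = FALSE)
    f <- function(y) {
      if (axis == "prey") joint_pdf(sol, table, xi, y, which)
      else joint_pdf(sol, table, y, xi, which)
    }
    i1 <- stats::integrate(f, ylo, comp_star, rel.tol = rel.tol,
                           abs.tol = 1e-12, subdivisions = 400L,
                           stop.on.error = FALSE)
    i2 <- stats::integrate(f, comp_star, yhi, rel.tol = rel.tol,
                           abs.tol = 1e-12, subdivisions = 400L,
                           stop.on.error = FALSE)
    i1$value + i2$value
  }, numeric(1L))
  prov <- if (which == "perturbation") "perturbation" else
    if (which == "gaussian") "gaussian" else "difference"
  structure(list(axis = axis, x = x, density = dens, provenance = prov),
            class = "lv_marginal")
}

#' @export
print.lv_marginal <- function(x, ...) {
  m <- trapz(x$x, x$density)
  cat(sprintf("Marginal PDF (%s axis, %s): %d points on [%.4g, %.4g]\n",
              x$axis, x$provenance, length(x$x), min(x$x), max(x$x)))
  cat(sprintf("  mass = %.6f, max density = %.6g at x = %.6g\n",
              m, max(x$density), x$x[which.max(x$density)]))
  invisible(x)
}

# trapezoid rule
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' L2 discrepancy between two marginal PDFs
#'
#' \eqn{\int_0^\infty (p_a(x) - p_b(x))^2 dx} by the trapezoid rule on
#' the union grid (each input interpolated there; regions where both
#' densities fall below 1e-12 contribute nothing).
#'
#' @param pdf_a,pdf_b two [marginal_pdf()] objects on the same axis.
#' @return scalar discrepancy.
#' @export
l2_error <- function(pdf_a, pdf_b) {
  stopifnot(inherits(pdf_a, "lv_marginal"), inherits(pdf_b, "lv_marginal"))
  if (pdf_a$axis != pdf_b$axis)
    stop("marginals live on different axes", call. = FALSE)
  xs <- sort(unique(c(pdf_a$x, pdf_b$x)))
  ya <- stats::approx(pdf_a$x, pdf_a$density, xs, yleft = 0,
                      yright = 0)$y
  yb <- stats::approx(pdf_b$x, pdf_b$density, xs, yleft = 0,
                      yright = 0)$y
  keep <- !(abs(ya) < 1e-12 & abs(yb) < 1e-12)
  if (!any(keep)) return(0)
  trapz(xs, (ya - yb)^2)
}

#' High-accuracy L2 discrepancy between perturbation and Gaussian marginals
#'
#' Computes the marginal of the *correction* density directly (one
#' quadrature of the signed difference), then integrates its square.
#' Subtracting two separately-computed marginals would lose precision
#' when the correction is orders of magnitude below the densities.
#'
#' @inheritParams marginal_pdf
#' @param n_x number of grid points for the squared-difference integral.
#' @return scalar \eqn{\int (p_{X_i} - p^G_{X_i})^2 dx_i}.
#' @export
l2_perturbation_vs_gaussian <- function(sol, table,
                                        axis = c("prey", "predator"),
                                        n_x = 400L, rel.tol = 1e-8) {
  rs <- resolve_sol(sol, table); sol <- rs$sol; table <- rs$table
  axis <- match.arg(axis)
  r_cut <- level_mass_cut(sol)
  ext <- level_extents(table$eff, r_cut)
  x <- if (axis == "prey")
    seq(ext[["x1_min"]], ext[["x1_max"]], length.out = n_x)
  else seq(ext[["x2_min"]], ext[["x2_max"]], length.out = n_x)
  d <- marginal_pdf(sol, table, axis, x, which = "difference",
                    r_cut = r_cut, rel.tol = rel.tol)
  trapz(d$x, d$density^2)
}

#' Stationary moments and relative fluctuations
#'
#' Means and variances of the population densities, computed on the
#' level grid as \eqn{E[h] = \int p_R(r)\,\langle h\rangle(r)\,dr}
#' (reusing the tabulated orbit averages of \eqn{x_i, x_i^2}); relative
#' fluctuations are coefficients of variation \eqn{\sqrt{Var}/E}. The
#' ratio \eqn{Var/E} is also reported (`var_over_mean_*`).
#'
#' @inheritParams joint_pdf
#' @param which `"perturbation"` or `"gaussian"`.
#' @return list with `mean_x1`, `mean_x2`, `var_x1`, `var_x2`,
#'   `relfluct_x1`, `relfluct_x2`, `var_over_mean_x1`,
#'   `var_over_mean_x2`.
#' @export
stationary_moments <- function(sol, table = NULL,
                               which = c("perturbation", "gaussian")) {
  rs <- resolve_sol(sol, table); sol <- rs$sol; table <- rs$table
  stopifnot(inherits(sol, "lv_stationary"), inherits(table, "orbit_table"))
  which <- match.arg(which)
  p <- if (which == "perturbation") sol$pR else sol$pG
  EE <- function(col) {
    h <- orbit_column(table, col, sol$r)
    mass_integral(sol$t, sol$r, p * h, sol$kappa)
  }
  m1 <- EE("x1"); m2 <- EE("x2")
  v1 <- EE("x1p2") - m1^2
  v2 <- EE("x2p2") - m2^2
  if (v1 < -1e-10 || v2 < -1e-10)
    stop("negative variance beyond tolerance: accuracy failure",
         call. = FALSE)
  v1 <- max(v1, 0); v2 <- max(v2, 0)
  list(mean_x1 = m1, mean_x2 = m2, var_x1 = v1, var_x2 = v2,
       relfluct_x1 = sqrt(v1) / m1, relfluct_x2 = sqrt(v2) / m2,
       var_over_mean_x1 = v1 / m1, var_over_mean_x2 = v2 / m2)
}
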