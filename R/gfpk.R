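# Stationary solution of the averaged generalized FPK equation for the
# first integral R, by the second-order perturbation scheme:
#   order-1:  -(A11bar p0)' + (1/2)(A21bar p0)'' = 0        (zero flux)
#   order-2:  same operator on p2, forced by the jump-noise terms
# All work is done on a dense grid uniform in t = log(r): the density mass
# concentrates near r = 0 and every quantity is smooth in log r.

# cumulative trapezoid of y dt
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# integral of f dr on the dense log grid plus the analytic sub-grid
# segment [0, r_lo] where f ~ f(r_lo) * (r/r_lo)^(kappa-1)
mass_integral <- function(t, r, f, kappa = 1) {
  sum((f[-1] * r[-1] + f[-length(f)] * r[-length(r)]) / 2 * diff(t)) +
    f[1] * r[1] / kappa
}

#' First-order (Gaussian-approximation) stationary density of the level
#'
#' Solves the zero-probability-flux equation \eqn{\bar A_{11} p_0 -
#' \tfrac12 (\bar A_{21} p_0)' = 0}: \eqn{p_0(r) = C\,e^{\Phi(r)}/\bar
#' A_{21}(r)} with \eqn{\Phi(r) = \int 2\bar A_{11}/\bar A_{21}\,du},
#' normalized to unit mass on \eqn{[0, \infty)}. Near \eqn{r = 0} the
#' density behaves like \eqn{r^{\kappa - 1}} with \eqn{\kappa = 2\bar
#' A_{11}(0)/\bar A_{21}'(0)}; the noise structure of this model gives
#' \eqn{\kappa = 1} (finite positive density at the equilibrium level),
#' and the sub-grid segment uses that power law.
#'
#' @param coeffs an [coefficient_functions()] object.
#' @param n_dense number of dense evaluation nodes (uniform in log r).
#' @return list with the dense grids `t` (= log r), `r`, the normalized
#'   density `p0`, the exponent `kappa`, the raw mass, and the estimated
#'   tail mass beyond `r_max`.
#' @export
solve_p0 <- function(coeffs, n_dense = 4001L) {
  stopifnot(inherits(coeffs, "lv_coeffs"))
  tab <- coeffs$table
  t <- seq(log(tab$r_lo), log(tab$r_max), length.out = n_dense)
  r <- exp(t)
  A11 <- coeffs$A11bar(r)
  A21 <- coeffs$A21bar(r)
  if (any(A21 <= 0))
    stop("A21bar must be positive on the open grid", call. = FALSE)
  # kappa from the leading behavior near zero; if A21bar does not vanish
  # at the origin (regular boundary, e.g. synthetic constant
  # coefficients), the density is simply finite there (kappa = 1)
  r0 <- tab$r_lo / 4
  if (coeffs$A21bar(r0) > 0.5 * coeffs$A21bar(tab$r_lo)) {
    kappa <- 1
  } else {
    kappa <- 2 * coeffs$A11bar(1e-12 * tab$r_lo) /
      (coeffs$A21bar(r0) / r0)
    if (kappa <= 0)
      stop("non-normalizable stationary density (kappa <= 0): ",
           "the model regime has no stationary first-integral law",
           call. = FALSE)
  }
  # Phi via cumulative trapezoid in t (dr = r dt)
  Phi <- cumtrapz(t, 2 * A11 / A21 * r)
  p0 <- exp(Phi - max(Phi)) / A21
  mass <- mass_integral(t, r, p0, kappa)
  p0 <- p0 / mass
  # tail mass estimate: exponential continuation at the local decay rate
  rate <- -2 * A11[n_dense] / A21[n_dense]
  tail <- if (rate > 0) p0[n_dense] / rate else Inf
  list(t = t, r = r, p0 = p0, kappa = kappa, mass = mass,
       tail_mass = tail)
}

# Derivatives (up to third) of a smooth function of r by local polynomial
# fits with a window scaled to r. Naive small-step differentiation of
# interpolants fails here: near r = 0 the chain-rule factors 1/r^k amplify
# interpolation noise catastrophically, while the underlying functions are
# analytic in r. A quartic least-squares fit over a window of half-width
# max(0.35 r, w_min) reads off derivatives at the noise floor of the
# function values instead.
local_poly_derivs <- function(f, r_eval, lo, hi, w_min = 0.02,
                              deg = 4L, npts = 9L) {
  half <- pmax(0.35 * r_eval, w_min)
  half <- pmin(half, (hi - lo) / 2)
  center <- pmin(pmax(r_eval, lo + half), hi - half)
  z <- seq(-1, 1, length.out = npts)
  X <- outer(z, 0:deg, `^`)
  P <- solve(crossprod(X), t(X))          # (deg+1) x npts projector
  xs <- center + outer(half, z)           # n x npts sample abscissae
  V <- matrix(f(as.vector(xs)), nrow = length(r_eval))
  C <- V %*% t(P)                         # n x (deg+1) poly coefficients
  z0 <- (r_eval - center) / half
  k <- 0:deg
  ev <- function(coef_mult, shift) {
    # evaluate sum_k coef_mult[k] * C[,k] * z0^(k-shift)
    acc <- numeric(length(r_eval))
    for (j in seq_along(k)) {
      kk <- k[j]
      if (kk >= shift)
        acc <- acc + coef_mult[j] * C[, j] * z0^(kk - shift)
    }
    acc
  }
  d0 <- ev(rep(1, deg + 1L), 0L)
  d1 <- ev(k, 1L) / half
  d2 <- ev(k * (k - 1L), 2L) / half^2
  d3 <- ev(k * (k - 1L) * (k - 2L), 3L) / half^3
  list(d0 = d0, d1 = d1, d2 = d2, d3 = d3)
}

#' Second-order jump correction of the stationary level density
#'
#' The order-two balance reads, once integrated in \eqn{r} (the
#' integration constant vanishes because every term decays at infinity),
#' \deqn{\tfrac12 \bar A_{21} p_2' + (\tfrac12 \bar A_{21}' - \bar
#'   A_{11}) p_2 = G, \quad G = \bar A_{12} p_0 - \tfrac12(\bar A_{22}
#'   p_0)' + \tfrac16(\bar A_{31} p_0)'' - \tfrac1{24}(\bar A_{41}
#'   p_0)'''.}
#' Since \eqn{p_0} solves the homogeneous equation, variation of
#' constants gives \eqn{p_2 = p_0 \int 2G/(\bar A_{21} p_0)\,du}; the
#' free multiple of \eqn{p_0} is fixed by \eqn{\int p_2\,dr = 0}.
#'
#' @param coeffs an [coefficient_functions()] object.
#' @param p0sol result of [solve_p0()].
#' @return numeric vector `p2` on the dense grid of `p0sol` (signed,
#'   zero total mass).
#' @export
solve_p2 <- function(coeffs, p0sol) {
  stopifnot(inherits(coeffs, "lv_coeffs"))
  t <- p0sol$t; r <- p0sol$r; p0 <- p0sol$p0
  A11 <- coeffs$A11bar(r); A21 <- coeffs$A21bar(r)
  # Derivatives of coefficient-times-p0 products are expanded with the
  # logarithmic derivative L = p0'/p0 (and its derivatives), obtained by
  # differentiating log p0 directly; p0 itself is never differentiated
  # through an interpolant:
  #   (f p0)'   = (f' + f L) p0
  #   (f p0)''  = (f'' + 2 f' L + f (L' + L^2)) p0
  #   (f p0)''' = (f''' + 3 f'' L + 3 f' (L' + L^2)
  #                + f (L'' + 3 L L' + L^3)) p0
  lo <- r[1]; hi <- r[length(r)]
  lp0_spline <- stats::splinefun(t, log(p0), method = "fmm")
  dL <- local_poly_derivs(function(x) lp0_spline(log(x)), r, lo, hi)
  L <- dL$d1; Lp <- dL$d2; Lpp <- dL$d3
  d22 <- local_poly_derivs(coeffs$A22bar, r, lo, hi)
  d31 <- local_poly_derivs(coeffs$A31bar, r, lo, hi)
  d41 <- local_poly_derivs(coeffs$A41bar, r, lo, hi)
  f22 <- coeffs$A22bar(r)
  f31 <- coeffs$A31bar(r)
  f41 <- coeffs$A41bar(r)
  G_over_p0 <- coeffs$A12bar(r) -
    0.5 * (d22$d1 + f22 * L) +
    (1 / 6) * (d31$d2 + 2 * d31$d1 * L + f31 * (Lp + L^2)) -
    (1 / 24) * (d41$d3 + 3 * d41$d2 * L + 3 * d41$d1 * (Lp + L^2) +
                  f41 * (Lpp + 3 * L * Lp + L^3))
  w <- cumtrapz(t, 2 * G_over_p0 * r / A21)
  p2 <- p0 * w
  # remove the homogeneous admixture: zero total mass
  p2 - p0 * mass_integral(t, r, p2, p0sol$kappa)
}

#' Assemble the stationary solution of the averaged equation
#'
#' Runs [solve_p0()] and [solve_p2()] and combines them into the
#' second-order perturbation density \eqn{p_R = p_0 + p_2} (the order-one
#' correction \eqn{p_1} vanishes: it satisfies the same homogeneous
#' zero-flux equation as \eqn{p_0}, and the normalization of the
#' perturbation series forces the admissible multiple of \eqn{p_0} to
#' zero) next to the Gaussian approximation \eqn{p_G = p_0}.
#'
#' @param coeffs an [coefficient_functions()] object.
#' @param n_dense dense grid size.
#' @return An object of class `"lv_stationary"`: dense grids and the
#'   normalized densities `p0`, `p2`, `pR`, `pG`, the exponent `kappa`,
#'   and diagnostics (tail mass, negative-mass fraction of `pR`).
#' @export
assemble_stationary <- function(coeffs, n_dense = 4001L) {
  p0sol <- solve_p0(coeffs, n_dense)
  p2 <- solve_p2(coeffs, p0sol)
  pR <- p0sol$p0 + p2
  mR <- mass_integral(p0sol$t, p0sol$r, pR, p0sol$kappa)
  pR <- pR / mR
  neg <- pmin(pR, 0)
  neg_mass <- -mass_integral(p0sol$t, p0sol$r, neg, p0sol$kappa)
  if (neg_mass > 1e-4)
    warning(sprintf(
      "perturbation density carries %.2g negative mass in the tails",
      neg_mass))
  structure(list(t = p0sol$t, r = p0sol$r,
                 p0 = p0sol$p0, p2 = p2, pR = pR, pG = p0sol$p0,
                 kappa = p0sol$kappa, mass0 = p0sol$mass,
                 tail_mass = p0sol$tail_mass, neg_mass = neg_mass,
                 coeffs = coeffs),
            class = "lv_stationary")
}

#' Evaluate a stationary level density at arbitrary levels
#'
#' @param sol an [assemble_stationary()] object.
#' @param r levels (>= 0, vectorized).
#' @param which `"perturbation"` (p0 + p2), `"gaussian"` (p0), or
#'   `"correction"` (p2).
#' @return density values; levels below the grid floor use the
#'   \eqn{r^{\kappa-1}} plateau (constant for \eqn{\kappa = 1}), levels
#'   beyond the grid return 0.
#' @export
stationary_density <- function(sol,
                               r,
                               which = c("perturbation", "gaussian",
                                         "correction")) {
  stopifnot(inherits(sol, "lv_stationary"))
  which <- match.arg(which)
  y <- switch(which, perturbation = sol$pR, gaussian = sol$pG,
              correction = sol$p2)
  sp <- stats::splinefun(sol$t, y, method = "fmm")
  out <- numeric(length(r))
  r_lo <- sol$r[1]; r_hi <- sol$r[length(sol$r)]
  inside <- r >= r_lo & r <= r_hi
  out[inside] <- sp(log(r[inside]))
  low <- r >= 0 & r < r_lo
  out[low] <- y[1] * (pmax(r[low], 1e-300) / r_lo)^(sol$kappa - 1)
  out[r > r_hi] <- 0
  out
}

#' @export
print.lv_stationary <- function(x, ...) {
  cat("Stationary first-integral densities (perturbation + Gaussian)\n")
  cat(sprintf("  grid: %d nodes, r in [%.3g, %.3g]; kappa = %.6g\n",
              length(x$r), min(x$r), max(x$r), x$kappa))
  cat(sprintf("  tail mass beyond r_max: %.3g; negative pR mass: %.3g\n",
              x$tail_mass, x$neg_mass))
  cat(sprintf("  max pG = %.6g, max pR = %.6g\n", max(x$pG), max(x$pR)))
  invisible(x)
}

#' Serialize the stationary solution to CSV
#'
#' Columns `r`, `p0`, `p2`, `pR`, `pG`.
#' @param sol an [assemble_stationary()] object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_stationary <- function(sol, path) {
  df <- data.frame(r = sol$r, p0 = sol$p0, p2 = sol$p2, pR = sol$pR,
                   pG = sol$pG)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
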