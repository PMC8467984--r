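#' Lotka-Volterra first integral
#'
#' The conserved quantity of the unperturbed system
#' \eqn{\dot x_1 = x_1(\bar a - \bar b x_2)}, \eqn{\dot x_2 = x_2(-c + \bar f
#' x_1)}:
#' \deqn{r(x_1, x_2) = \bar f x_1 - c - c\log(\bar f x_1/c) + \bar b x_2 -
#'   \bar a - \bar a \log(\bar b x_2/\bar a).}
#' \eqn{r \ge 0} with equality exactly at the coexistence equilibrium
#' \eqn{(c/\bar f, \bar a/\bar b)}; its level sets are the closed orbits.
#'
#' @inheritParams percapita_drift
#' @return numeric vector of level values (vectorized over the state).
#' @export
first_integral <- function(eff, x1, x2) {
  stopifnot(inherits(eff, "lv_eff"))
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("state must be strictly positive", call. = FALSE)
  phi1(eff, x1) + phi2(eff, x2)
}

# prey / predator halves of the first integral; each is convex with
# minimum 0 at the corresponding equilibrium coordinate
phi1 <- function(eff, x1) {
  eff$f_bar * x1 - eff$c - eff$c * log(eff$f_bar * x1 / eff$c)
}
phi2 <- function(eff, x2) {
  eff$b_bar * x2 - eff$a_bar - eff$a_bar * log(eff$b_bar * x2 / eff$a_bar)
}

# solve phi(x) = v for the branch below (lower=TRUE) or above the minimum.
# phi(x) = k*x - m - m*log(k*x/m) with minimum at x = m/k.
phi_invert <- function(k, m, v, lower, tol = 1e-14) {
  xstar <- m / k
  if (v < 0) stop("level value must be nonnegative", call. = FALSE)
  if (v == 0) return(xstar)
  f <- function(x) k * x - m - m * log(k * x / m) - v
  # bracket: quadratic estimate half-width sqrt(2*m*v)/k, then expand
  w <- sqrt(2 * m * v) / k
  if (lower) {
    lo <- max(xstar - w, xstar * 1e-12)
    while (f(lo) < 0) lo <- lo / 2
    hi <- xstar
  } else {
    hi <- xstar + w
    while (f(hi) < 0) hi <- xstar + 2 * (hi - xstar)
    lo <- xstar
  }
  uniroot(f, c(lo, hi), tol = tol * xstar, maxiter = 200L)$root
}

#' Extents of a first-integral level curve
#'
#' For a level \eqn{r > 0}, returns the prey interval
#' \eqn{[x_{1,\min}, x_{1,\max}]} and predator interval
#' \eqn{[x_{2,\min}, x_{2,\max}]} reached on the closed orbit
#' \eqn{r(x_1,x_2) = r}: the roots of \eqn{\varphi_1(x_1) = r} and
#' \eqn{\varphi_2(x_2) = r} around the equilibrium coordinates.
#'
#' @inheritParams percapita_drift
#' @param r level value (> 0).
#' @return named numeric vector `x1_min`, `x1_max`, `x2_min`, `x2_max`.
#' @export
level_extents <- function(eff, r) {
  stopifnot(inherits(eff, "lv_eff"))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("level 'r' must be a positive scalar", call. = FALSE)
  c(x1_min = phi_invert(eff$f_bar, eff$c, r, lower = TRUE),
    x1_max = phi_invert(eff$f_bar, eff$c, r, lower = FALSE),
    x2_min = phi_invert(eff$b_bar, eff$a_bar, r, lower = TRUE),
    x2_max = phi_invert(eff$b_bar, eff$a_bar, r, lower = FALSE))
}

#' Period of the small-amplitude (harmonic) limit
#'
#' As \eqn{r \to 0} the closed orbits shrink onto the equilibrium and the
#' period tends to \eqn{2\pi/\sqrt{\bar a c}}.
#'
#' @inheritParams percapita_drift
#' @return scalar period.
#' @export
harmonic_period <- function(eff) 2 * pi / sqrt(eff$a_bar * eff$c)

#' Trace one closed orbit and accumulate time averages
#'
#' Integrates the unperturbed system in log coordinates
#' \eqn{(u, v) = (\log x_1, \log x_2)}, where the flow is canonically
#' Hamiltonian with Hamiltonian \eqn{r(e^u, e^v)} (conservation is excellent
#' and positivity automatic). Starting from the section point
#' \eqn{(x_{1,\max}(r),\ \bar a/\bar b)}, it runs until first return to the
#' section \eqn{\{x_2 = \bar a/\bar b\}} with the starting crossing
#' direction (two half-legs terminated by root finding), accumulating the
#' quasi-period \eqn{T(r) = \oint dt} and \eqn{\oint h_j\,dt} for each
#' registered integrand.
#'
#' @inheritParams level_extents
#' @param integrands named list of functions `function(x1, x2)` to be
#'   orbit-averaged.
#' @param rtol,atol integrator tolerances.
#' @return list with `T` (period) and `avg` (named vector of time averages
#'   \eqn{\langle h_j\rangle = (1/T)\oint h_j dt}).
#' @export
trace_orbit <- function(eff, r, integrands = list(),
                        rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(eff, "lv_eff"))
  if (r <= 0) stop("level 'r' must be positive", call. = FALSE)
  ni <- length(integrands)
  if (ni && is.null(names(integrands)))
    stop("integrands must be a named list", call. = FALSE)
  a_bar <- eff$a_bar; b_bar <- eff$b_bar; f_bar <- eff$f_bar; cc <- eff$c
  vstar <- log(a_bar / b_bar)
  ext <- level_extents(eff, r)
  y0 <- c(u = log(ext[["x1_max"]]), v = vstar,
          if (ni) stats::setNames(numeric(ni), names(integrands)))

  deriv <- function(t, y, parms) {
    x1 <- exp(y[1L]); x2 <- exp(y[2L])
    du <- a_bar - b_bar * x2
    dv <- -cc + f_bar * x1
    if (ni) {
      dI <- vapply(integrands, function(h) h(x1, x2), numeric(1L))
      list(c(du, dv, dI))
    } else list(c(du, dv))
  }
  rootfun <- function(t, y, parms) y[2L] - vstar

  Th <- harmonic_period(eff)
  horizon <- 50 * Th * (1 + r)      # safety horizon for one leg
  nudge <- 0.01 * Th                # leave the section before root-arming
  leg <- function(y0) {
    pre <- deSolve::lsoda(y0, times = c(0, nudge), func = deriv,
                          rtol = rtol, atol = atol, maxsteps = 100000L)
    y1 <- pre[nrow(pre), -1L]
    out <- deSolve::lsodar(y1, times = c(0, horizon), func = deriv,
                           rootfunc = rootfun, rtol = rtol, atol = atol,
                           maxsteps = 100000L)
    if (is.null(attr(out, "troot")) || length(attr(out, "troot")) == 0L)
      stop(sprintf(paste0("orbit at level r = %g failed to return to the ",
                          "section within the safety horizon"), r),
           call. = FALSE)
    list(t = nudge + attr(out, "troot"), y = out[nrow(out), -1L])
  }
  l1 <- leg(y0)                     # half period: crossing on the far side
  l2 <- leg(l1$y)                   # back to the starting section
  Tr <- l1$t + l2$t
  avg <- if (ni) {
    # aux states accumulate across both legs; l2 carries the full circuit
    stats::setNames(as.numeric(unlist(l2$y[-(1:2)])) / Tr,
                    names(integrands))
  } else numeric(0)
  list(T = Tr, avg = avg)
}

# quasi-period via the singular quadrature T(r) = \oint dx1/(x1(a_bar -
# b_bar x2)): split over the two x2-branches of the level curve, with the
# inverse-square-root endpoint singularities removed by the substitution
# x1 = x_end -/+ t^2. Retained as an independent cross-check of trace_orbit.
period_quadrature <- function(eff, r, rel.tol = 1e-10) {
  ext <- level_extents(eff, r)
  a_bar <- eff$a_bar; b_bar <- eff$b_bar
  branch_gap <- function(x1) {
    # 1/(a-b*x2_lower) - 1/(a-b*x2_upper), x2 branches of phi2 = r - phi1
    vapply(x1, function(x) {
      rho <- r - phi1(eff, x)
      if (rho <= 0) return(0)
      x2lo <- phi_invert(b_bar, a_bar, rho, lower = TRUE)
      x2hi <- phi_invert(b_bar, a_bar, rho, lower = FALSE)
      1 / (a_bar - b_bar * x2lo) - 1 / (a_bar - b_bar * x2hi)
    }, numeric(1L))
  }
  xstar <- eff$x1_star
  # left piece: x1 = x1_min + t^2, dx1 = 2t dt
  f_left <- function(t) 2 * t * branch_gap(ext[["x1_min"]] + t^2) /
    (ext[["x1_min"]] + t^2)
  # right piece: x1 = x1_max - t^2
  f_right <- function(t) 2 * t * branch_gap(ext[["x1_max"]] - t^2) /
    (ext[["x1_max"]] - t^2)
  i1 <- stats::integrate(f_left, 0, sqrt(xstar - ext[["x1_min"]]),
                         rel.tol = rel.tol, subdivisions = 500L)$value
  i2 <- stats::integrate(f_right, 0, sqrt(ext[["x1_max"]] - xstar),
                         rel.tol = rel.tol, subdivisions = 500L)$value
  i1 + i2
}

#' Tabulate orbit geometry and time averages over a grid of levels
#'
#' Builds the per-level table that the averaged-equation coefficients are
#' assembled from: the quasi-period \eqn{T(r)} and the orbit averages of the
#' monomials \eqn{x_1^k, x_2^k} (k = 1..4) plus the noise-independent part
#' of the drift correction of the first integral (see
#' [coefficient_functions()]). The grid is logarithmically spaced so that
#' the region near the equilibrium (where the stationary density mass
#' concentrates) is densely resolved.
#'
#' @inheritParams percapita_drift
#' @param r_max largest tabulated level.
#' @param n_levels number of grid levels (>= 50).
#' @param r_lo smallest tabulated level; defaults to
#'   `1e-4 * a_bar * c` (deep inside the harmonic regime).
#' @param extra_integrands optional named list of additional integrands.
#' @return An object of class `"orbit_table"`: list with `r` (grid),
#'   `T`, matrix `avg` (one column per integrand), `eff`, and spline
#'   interpolants in `log(r)` for every column.
#' @export
build_orbit_table <- function(eff, r_max, n_levels = 101L,
                              r_lo = NULL, extra_integrands = list()) {
  stopifnot(inherits(eff, "lv_eff"))
  if (n_levels < 50L) stop("n_levels must be >= 50", call. = FALSE)
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  if (is.null(r_lo)) r_lo <- 1e-4 * eff$a_bar * eff$c
  if (r_lo >= r_max) stop("r_lo must be below r_max", call. = FALSE)

  base_int <- list(
    x1  = function(x1, x2) x1,
    x1p2 = function(x1, x2) x1^2,
    x1p3 = function(x1, x2) x1^3,
    x1p4 = function(x1, x2) x1^4,
    x2  = function(x1, x2) x2,
    x2p2 = function(x1, x2) x2^2,
    x2p3 = function(x1, x2) x2^3,
    x2p4 = function(x1, x2) x2^4,
    U0a = local({
      e <- eff; s <- eff$params$s
      function(x1, x2) {
        g <- g_corrections(e, x1, x2)
        A11 <- e$f_bar * x1 - e$c
        A21 <- e$b_bar * x2 - e$a_bar
        A11 * (-(s / e$f_bar) * A11 + g$g1) + A21 * g$g2
      }
    }))
  ints <- c(base_int, extra_integrands)

  r_grid <- exp(seq(log(r_lo), log(r_max), length.out = n_levels))
  Tvec <- numeric(n_levels)
  avg <- matrix(NA_real_, n_levels, length(ints),
                dimnames = list(NULL, names(ints)))
  for (i in seq_len(n_levels)) {
    tr <- trace_orbit(eff, r_grid[i], ints)
    Tvec[i] <- tr$T
    avg[i, ] <- tr$avg
  }
  lt <- log(r_grid)
  splines <- c(list(T = stats::splinefun(lt, Tvec, method = "fmm")),
               lapply(colnames(avg), function(nm)
                 stats::splinefun(lt, avg[, nm], method = "fmm")))
  names(splines) <- c("T", colnames(avg))
  structure(list(r = r_grid, T = Tvec, avg = avg, eff = eff,
                 splines = splines, r_lo = r_lo, r_max = r_max),
            class = "orbit_table")
}

#' @export
print.orbit_table <- function(x, ...) {
  cat(sprintf("Orbit table: %d levels, r in [%.3g, %.3g]\n",
              length(x$r), min(x$r), max(x$r)))
  cat(sprintf("  period T in [%.6g, %.6g] (harmonic limit %.6g)\n",
              min(x$T), max(x$T), harmonic_period(x$eff)))
  cat(sprintf("  averaged integrands: %s\n",
              paste(colnames(x$avg), collapse = ", ")))
  invisible(x)
}

# evaluate a tabulated column at arbitrary r (vectorized); below the grid
# floor, values fall back to their harmonic-limit behavior: T -> harmonic
# period, monomial averages -> equilibrium values, U0a -> 0 linearly.
orbit_column <- function(table, name, r) {
  sp <- table$splines[[name]]
  if (is.null(sp)) stop(sprintf("column '%s' not tabulated", name),
                        call. = FALSE)
  out <- numeric(length(r))
  lo <- r < table$r_lo
  out[!lo] <- sp(log(r[!lo]))
  if (any(lo)) {
    eff <- table$eff
    v_lo <- sp(log(table$r_lo))
    v0 <- switch(name,
                 T = harmonic_period(eff),
                 x1 = eff$x1_star, x1p2 = eff$x1_star^2,
                 x1p3 = eff$x1_star^3, x1p4 = eff$x1_star^4,
                 x2 = eff$x2_star, x2p2 = eff$x2_star^2,
                 x2p3 = eff$x2_star^3, x2p4 = eff$x2_star^4,
                 U0a = 0,
                 v_lo)
    # linear blend in r between the analytic limit at 0 and the first node
    out[lo] <- v0 + (v_lo - v0) * r[lo] / table$r_lo
  }
  out
}

#' Serialize an orbit table to CSV
#'
#' Columns `r`, `T`, and `avg_<name>` per registered average.
#' @param table an [build_orbit_table()] object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_orbit_table <- function(table, path) {
  df <- data.frame(r = table$r, T = table$T, table$avg,
                   check.names = FALSE)
  names(df) <- c("r", "T", paste0("avg_", colnames(table$avg)))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
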