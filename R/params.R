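#' Model parameters for the two predator-prey variants
#'
#' Defines one ecosystem: the classic Lotka-Volterra rates plus a weak
#' self-competition term and one of two weak interaction modifications,
#' * `"saturation"`: per-predator consumption saturates in prey density,
#'   interaction `b*x1*x2/(1 + A*x1)` (abundant prey);
#' * `"competition"`: predators compete for limited prey, interaction
#'   `b*x1*x2/(1 + B*x2)` (large predator population).
#'
#' The self-competition coefficient `s` and the saturation/competition
#' coefficients `A`, `B` are *effective* parameters: the perturbation
#' bookkeeping parameter of the small-noise analysis is absorbed into them,
#' so they are exactly the numbers a study would quote (e.g. `A = 0.05`).
#'
#' @param case `"saturation"` or `"competition"`.
#' @param a prey per-capita birth rate (1/time, > 0).
#' @param b predation coefficient (> 0).
#' @param c predator per-capita death rate (> 0).
#' @param f prey-to-predator conversion coefficient (> 0).
#' @param s effective self-competition coefficient (>= 0).
#' @param A effective predator-saturation coefficient (>= 0, saturation case
#'   only).
#' @param B effective predator-competition coefficient (>= 0, competition
#'   case only).
#' @return An object of class `"lv_params"`.
#' @seealso [effective_params()], [lvsa()]
#' @examples
#' lv_params("saturation", a = 1, b = 1, c = 0.5, f = 0.5, s = 0.1, A = 0.05)
#' @export
lv_params <- function(case = c("saturation", "competition"),
                      a, b, c, f, s = 0, A = 0, B = 0) {
  case <- match.arg(case)
  chk <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm),
           call. = FALSE)
    if (strict && x <= 0)
      stop(sprintf("parameter '%s' must be strictly positive", nm),
           call. = FALSE)
    if (!strict && x < 0)
      stop(sprintf("parameter '%s' must be nonnegative", nm), call. = FALSE)
    as.numeric(x)
  }
  a <- chk(a, "a"); b <- chk(b, "b"); c <- chk(c, "c"); f <- chk(f, "f")
  s <- chk(s, "s", strict = FALSE)
  A <- chk(A, "A", strict = FALSE)
  B <- chk(B, "B", strict = FALSE)
  if (case == "saturation" && B != 0)
    stop("'B' must be 0 in the saturation case (use 'A')", call. = FALSE)
  if (case == "competition" && A != 0)
    stop("'A' must be 0 in the competition case (use 'B')", call. = FALSE)
  if (case == "saturation" && f - c * A <= 0)
    stop("invalid parameters: effective conversion f - c*A must be positive",
         call. = FALSE)
  structure(list(case = case, a = a, b = b, c = c, f = f,
                 s = s, A = A, B = B),
            class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf("Predator-prey model (%s case)\n", x$case))
  cat(sprintf("  a = %g, b = %g, c = %g, f = %g\n", x$a, x$b, x$c, x$f))
  extra <- if (x$case == "saturation") sprintf("A = %g", x$A)
           else sprintf("B = %g", x$B)
  cat(sprintf("  s = %g, %s\n", x$s, extra))
  invisible(x)
}

#' Effective (barred) parameters of the unified model form
#'
#' Both model variants can be written in a common form
#' \deqn{\dot x_1 = x_1[\bar a - \bar b x_2 - (s/\bar f)(-c + \bar f x_1) +
#'   g_1], \quad \dot x_2 = x_2[-c + \bar f x_1 + g_2],}
#' where the correction rates \eqn{g_1, g_2} vanish when the saturation /
#' competition coefficient is zero. This function computes the barred
#' parameters:
#' * saturation: \eqn{\bar f = f - cA}, \eqn{\bar b = b\bar f / f},
#'   \eqn{\bar a = a - s c/\bar f};
#' * competition: the simultaneous solution of \eqn{\bar a = a - sc/\bar f},
#'   \eqn{\bar b = b - \bar a B}, \eqn{\bar f = f \bar b / b}, obtained as the
#'   positive root of the quadratic
#'   \eqn{\bar b^2 - (b - aB)\bar b - Bscb/f = 0}.
#'
#' The interior equilibrium of the unified form is
#' \eqn{(c/\bar f,\ \bar a/\bar b)}.
#'
#' @param params an [lv_params()] object.
#' @return An object of class `"lv_eff"`: list with `a_bar`, `b_bar`,
#'   `f_bar`, `c`, the equilibrium `x1_star`, `x2_star`, and the originating
#'   `params`.
#' @examples
#' effective_params(lv_params("saturation", 1, 1, 0.5, 0.5, s = 0.1, A = 0.05))
#' @export
effective_params <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  a <- params$a; b <- params$b; c <- params$c; f <- params$f
  s <- params$s
  if (params$case == "saturation") {
    A <- params$A
    f_bar <- f - c * A
    if (f_bar <= 0)
      stop("invalid parameters: f_bar = f - c*A is not positive",
           call. = FALSE)
    b_bar <- b * f_bar / f
    a_bar <- a - s * c / f_bar
  } else {
    B <- params$B
    # b_bar^2 - (b - a*B) b_bar - B*s*c*b/f = 0, take the positive root
    # (the product of roots is -B*s*c*b/f <= 0, so the other root is <= 0)
    p <- b - a * B
    q <- B * s * c * b / f
    b_bar <- (p + sqrt(p * p + 4 * q)) / 2
    if (b_bar <= 0)
      stop("invalid parameters: effective predation b_bar is not positive",
           call. = FALSE)
    f_bar <- f * b_bar / b
    a_bar <- a - s * c / f_bar
  }
  if (a_bar <= 0)
    stop("invalid parameters: effective growth rate a_bar is not positive",
         call. = FALSE)
  if (b_bar <= 0)
    stop("invalid parameters: effective predation b_bar is not positive",
         call. = FALSE)
  structure(list(a_bar = a_bar, b_bar = b_bar, f_bar = f_bar, c = c,
                 x1_star = c / f_bar, x2_star = a_bar / b_bar,
                 params = params),
            class = "lv_eff")
}

#' @export
print.lv_eff <- function(x, ...) {
  cat(sprintf("Unified-form effective parameters (%s case)\n",
              x$params$case))
  cat(sprintf("  a_bar = %.10g, b_bar = %.10g, f_bar = %.10g, c = %g\n",
              x$a_bar, x$b_bar, x$f_bar, x$c))
  cat(sprintf("  equilibrium (x1*, x2*) = (%.10g, %.10g)\n",
              x$x1_star, x$x2_star))
  invisible(x)
}

#' Exact per-capita growth rates of the original models
#'
#' Evaluates the per-capita rates \eqn{h_1 = \dot x_1/x_1},
#' \eqn{h_2 = \dot x_2/x_2} of the *original* (un-unified) deterministic
#' model at a state. These are the ground truth for the consistency checks
#' of the unified form and the exact drift used by the simulator.
#'
#' @param eff an [effective_params()] object (carries the raw parameters).
#' @param x1,x2 strictly positive state (vectorized).
#' @return list with numeric `h1`, `h2`.
#' @export
percapita_drift <- function(eff, x1, x2) {
  stopifnot(inherits(eff, "lv_eff"))
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("state must be strictly positive", call. = FALSE)
  p <- eff$params
  if (p$case == "saturation") {
    den <- 1 + p$A * x1
    h1 <- p$a - p$s * x1 - p$b * x2 / den
    h2 <- -p$c + p$f * x1 / den
  } else {
    den <- 1 + p$B * x2
    h1 <- p$a - p$s * x1 - p$b * x2 / den
    h2 <- -p$c + p$f * x1 / den
  }
  list(h1 = h1, h2 = h2)
}

#' Per-capita correction rates of the unified form
#'
#' The rates \eqn{g_1, g_2} that close the gap between the unified-form
#' skeleton and the original model:
#' \deqn{h_1 = \bar a - \bar b x_2 - (s/\bar f)(-c + \bar f x_1) + g_1,
#'   \qquad h_2 = -c + \bar f x_1 + g_2.}
#' Saturation case: \eqn{g_1 = (\bar b/\bar f) A x_2 (\bar f x_1 - c)/(1 +
#' A x_1)}, \eqn{g_2 = -A x_1 (\bar f x_1 - c)/(1 + A x_1)}. Competition
#' case: \eqn{g_1 = -B x_2 (\bar a - \bar b x_2)/(1 + B x_2)},
#' \eqn{g_2 = (\bar f/\bar b) B x_1 (\bar a - \bar b x_2)/(1 + B x_2)}.
#'
#' @inheritParams percapita_drift
#' @return list with numeric `g1`, `g2` (vectorized).
#' @export
g_corrections <- function(eff, x1, x2) {
  stopifnot(inherits(eff, "lv_eff"))
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("state must be strictly positive", call. = FALSE)
  p <- eff$params
  if (p$case == "saturation") {
    A <- p$A
    fac <- (eff$f_bar * x1 - eff$c) / (1 + A * x1)
    g1 <- (eff$b_bar / eff$f_bar) * A * x2 * fac
    g2 <- -A * x1 * fac
  } else {
    B <- p$B
    fac <- (eff$a_bar - eff$b_bar * x2) / (1 + B * x2)
    g1 <- -B * x2 * fac
    g2 <- (eff$f_bar / eff$b_bar) * B * x1 * fac
  }
  list(g1 = g1, g2 = g2)
}

# unified-form per-capita rates reconstructed from barred parameters + g;
# used by tests and by the first-integral drift bookkeeping
unified_drift <- function(eff, x1, x2) {
  g <- g_corrections(eff, x1, x2)
  s <- eff$params$s
  h1 <- eff$a_bar - eff$b_bar * x2 -
    (s / eff$f_bar) * (-eff$c + eff$f_bar * x1) + g$g1
  h2 <- -eff$c + eff$f_bar * x1 + g$g2
  list(h1 = h1, h2 = h2)
}
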