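#' Noise parameters: Gaussian intensities and Poisson jump statistics
#'
#' The prey growth rate and predator death rate are perturbed by
#' independent Gaussian white noises (intensities \eqn{2D_i}) and
#' independent Poisson white noises (mean arrival rates \eqn{\lambda_i},
#' zero-mean Gaussian impulse magnitudes with variance \eqn{E[Y_i^2]}).
#' All stored values are *effective*: the small-perturbation bookkeeping
#' parameter is absorbed, exactly as quoted in applications. Because study
#' conditions are commonly quoted as the full Gaussian intensity
#' \eqn{2D_i}, the constructor accepts either `D1`/`D2` (the half
#' intensity) or `two_D1`/`two_D2` (the printed intensity; halved
#' internally) — the two conventions are mutually exclusive.
#'
#' The impulse magnitudes are zero-mean Gaussian, so the effective fourth
#' moments are `3 * m^2` and are never stored separately.
#'
#' @param D1,D2 effective Gaussian half-intensities (>= 0).
#' @param two_D1,two_D2 alternatively, the full printed intensities
#'   \eqn{2D_i}.
#' @param lambda1,lambda2 Poisson mean arrival rates (>= 0; 0 = no jumps).
#' @param m1,m2 effective jump-magnitude variances \eqn{E[Y_i^2]} (>= 0).
#' @return An object of class `"lv_noise"` with fields `D1`, `D2`,
#'   `lambda1`, `lambda2`, `m1`, `m2`.
#' @examples
#' lv_noise(two_D1 = 0.001, two_D2 = 0.001, lambda1 = 0.1, lambda2 = 0.1,
#'          m1 = 0.08, m2 = 0.08)
#' @export
lv_noise <- function(D1 = NULL, D2 = NULL, two_D1 = NULL, two_D2 = NULL,
                     lambda1 = 0, lambda2 = 0, m1 = 0, m2 = 0) {
  if (!is.null(D1) && !is.null(two_D1) || !is.null(D2) && !is.null(two_D2))
    stop("give either D_i or two_D_i, not both", call. = FALSE)
  if (!is.null(two_D1)) D1 <- two_D1 / 2
  if (!is.null(two_D2)) D2 <- two_D2 / 2
  if (is.null(D1)) D1 <- 0
  if (is.null(D2)) D2 <- 0
  vals <- c(D1 = D1, D2 = D2, lambda1 = lambda1, lambda2 = lambda2,
            m1 = m1, m2 = m2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise parameters must be finite and nonnegative", call. = FALSE)
  structure(as.list(vals), class = "lv_noise")
}

#' @export
print.lv_noise <- function(x, ...) {
  cat("Noise parameters (effective form)\n")
  cat(sprintf("  Gaussian: 2D1 = %g, 2D2 = %g\n", 2 * x$D1, 2 * x$D2))
  cat(sprintf("  Poisson:  lambda = (%g, %g), E[Y^2] = (%g, %g)\n",
              x$lambda1, x$lambda2, x$m1, x$m2))
  cat(sprintf("  jump intensities lambda*E[Y^2] = (%g, %g)\n",
              x$lambda1 * x$m1, x$lambda2 * x$m2))
  invisible(x)
}

#' Taylor coefficients of the first-integral jump response
#'
#' A jump of the log-population by \eqn{Y} changes the first integral by
#' \eqn{\sum_k A_{ik} Y^k}; the coefficients are
#' \eqn{A_{11} = \bar f x_1 - c}, \eqn{A_{12} = \bar f x_1/2},
#' \eqn{A_{13} = \bar f x_1/6}, \eqn{A_{14} = \bar f x_1/24} for the prey
#' channel and \eqn{A_{21} = \bar b x_2 - \bar a}, \eqn{A_{22} = \bar b
#' x_2/2}, \eqn{A_{23} = \bar b x_2/6}, \eqn{A_{24} = \bar b x_2/24} for
#' the predator channel.
#'
#' @inheritParams percapita_drift
#' @return named list of the eight coefficients (vectorized).
#' @export
jump_polynomials <- function(eff, x1, x2) {
  stopifnot(inherits(eff, "lv_eff"))
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("state must be strictly positive", call. = FALSE)
  fx <- eff$f_bar * x1
  bx <- eff$b_bar * x2
  list(A11 = fx - eff$c, A12 = fx / 2, A13 = fx / 6, A14 = fx / 24,
       A21 = bx - eff$a_bar, A22 = bx / 2, A23 = bx / 6, A24 = bx / 24)
}

#' Drift correction of the first integral
#'
#' The order-\eqn{\epsilon^2} drift acquired by the first integral
#' \eqn{R(X_1, X_2)} from self-competition, the saturation/competition
#' corrections, and the Wong-Zakai / Ito corrections of the Gaussian
#' noises:
#' \deqn{U_0 = (\bar f x_1 - c)\left[-\tfrac{s}{\bar f}(-c + \bar f x_1) +
#'   g_1 + D_1\right] + c D_1 + (\bar b x_2 - \bar a)[g_2 + D_2] +
#'   \bar a D_2.}
#'
#' @inheritParams percapita_drift
#' @param noise an [lv_noise()] object.
#' @return numeric vector (vectorized over the state).
#' @export
drift_correction_U0 <- function(eff, noise, x1, x2) {
  stopifnot(inherits(eff, "lv_eff"), inherits(noise, "lv_noise"))
  g <- g_corrections(eff, x1, x2)
  s <- eff$params$s
  A11 <- eff$f_bar * x1 - eff$c
  A21 <- eff$b_bar * x2 - eff$a_bar
  A11 * (-(s / eff$f_bar) * A11 + g$g1 + noise$D1) + eff$c * noise$D1 +
    A21 * (g$g2 + noise$D2) + eff$a_bar * noise$D2
}

#' Averaged drift, diffusion and jump coefficients on the level sets
#'
#' Assembles the coefficients of the averaged generalized
#' Fokker-Planck-Kolmogorov equation for the first integral as functions
#' of the level \eqn{r}, from the orbit table's time averages
#' \eqn{\langle x_i^k\rangle(r)} and the noise parameters:
#' \deqn{\bar A_{11} = \langle U_0\rangle + \lambda_1 m_1\langle
#'   A_{12}\rangle + \lambda_2 m_2\langle A_{22}\rangle,}
#' \deqn{\bar A_{21} = \langle A_{11}^2\rangle(2D_1 + \lambda_1 m_1) +
#'   \langle A_{21}^2\rangle(2D_2 + \lambda_2 m_2),}
#' and the jump-specific higher coefficients \eqn{\bar A_{12}, \bar
#' A_{22}, \bar A_{31}, \bar A_{41}} proportional to the fourth impulse
#' moments \eqn{3 m_i^2 \lambda_i}. Every average of a polynomial in
#' \eqn{x_1} (or \eqn{x_2}) alone is expanded over the tabulated monomial
#' averages, so one orbit table serves any noise setting.
#'
#' @param eff an [effective_params()] object.
#' @param noise an [lv_noise()] object.
#' @param table an [build_orbit_table()] object for the same `eff`.
#' @return An object of class `"lv_coeffs"`: list of vectorized functions
#'   of `r` (`A11bar`, `A12bar`, `A21bar`, `A22bar`, `A31bar`, `A41bar`),
#'   plus the node values on the table grid.
#' @export
coefficient_functions <- function(eff, noise, table) {
  stopifnot(inherits(eff, "lv_eff"), inherits(noise, "lv_noise"),
            inherits(table, "orbit_table"))
  need <- c("x1", "x1p2", "x1p3", "x1p4", "x2", "x2p2", "x2p3", "x2p4",
            "U0a")
  missing <- setdiff(need, colnames(table$avg))
  if (length(missing))
    stop(sprintf("orbit table lacks required integrands: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  fb <- eff$f_bar; bb <- eff$b_bar; cc <- eff$c; ab <- eff$a_bar
  la1 <- noise$lambda1; la2 <- noise$lambda2
  m1 <- noise$m1; m2 <- noise$m2
  y4_1 <- 3 * m1^2    # effective fourth impulse moments (Gaussian Y)
  y4_2 <- 3 * m2^2
  g1 <- 2 * noise$D1 + la1 * m1   # total prey-channel intensity
  g2 <- 2 * noise$D2 + la2 * m2

  col <- function(nm, r) orbit_column(table, nm, r)
  fns <- list(
    A11bar = function(r) {
      u0 <- col("U0a", r) +
        noise$D1 * (fb * col("x1", r) - cc + cc) +
        noise$D2 * (bb * col("x2", r) - ab + ab)
      u0 + la1 * m1 * fb * col("x1", r) / 2 +
        la2 * m2 * bb * col("x2", r) / 2
    },
    A12bar = function(r) {
      y4_1 * la1 * fb * col("x1", r) / 24 +
        y4_2 * la2 * bb * col("x2", r) / 24
    },
    A21bar = function(r) {
      a11sq <- fb^2 * col("x1p2", r) - 2 * cc * fb * col("x1", r) + cc^2
      a21sq <- bb^2 * col("x2p2", r) - 2 * ab * bb * col("x2", r) + ab^2
      a11sq * g1 + a21sq * g2
    },
    A22bar = function(r) {
      # <A12^2 + 2 A11 A13> = (7/12) fb^2 <x1^2> - (1/3) c fb <x1>
      t1 <- (7 / 12) * fb^2 * col("x1p2", r) -
        (1 / 3) * cc * fb * col("x1", r)
      t2 <- (7 / 12) * bb^2 * col("x2p2", r) -
        (1 / 3) * ab * bb * col("x2", r)
      y4_1 * la1 * t1 + y4_2 * la2 * t2
    },
    A31bar = function(r) {
      # <3 A11^2 A12> = (3 fb/2)(fb^2 <x1^3> - 2 c fb <x1^2> + c^2 <x1>)
      t1 <- (3 * fb / 2) * (fb^2 * col("x1p3", r) -
                              2 * cc * fb * col("x1p2", r) +
                              cc^2 * col("x1", r))
      t2 <- (3 * bb / 2) * (bb^2 * col("x2p3", r) -
                              2 * ab * bb * col("x2p2", r) +
                              ab^2 * col("x2", r))
      y4_1 * la1 * t1 + y4_2 * la2 * t2
    },
    A41bar = function(r) {
      t1 <- fb^4 * col("x1p4", r) - 4 * cc * fb^3 * col("x1p3", r) +
        6 * cc^2 * fb^2 * col("x1p2", r) - 4 * cc^3 * fb * col("x1", r) +
        cc^4
      t2 <- bb^4 * col("x2p4", r) - 4 * ab * bb^3 * col("x2p3", r) +
        6 * ab^2 * bb^2 * col("x2p2", r) - 4 * ab^3 * bb * col("x2", r) +
        ab^4
      y4_1 * la1 * t1 + y4_2 * la2 * t2
    })

  nodes <- data.frame(r = table$r)
  for (nm in names(fns)) nodes[[nm]] <- fns[[nm]](table$r)
  structure(c(fns, list(nodes = nodes, eff = eff, noise = noise,
                        table = table)),
            class = "lv_coeffs")
}

#' @export
print.lv_coeffs <- function(x, ...) {
  cat("Averaged GFPK coefficients on the first-integral levels\n")
  cat(sprintf("  grid: %d levels, r in [%.3g, %.3g]\n",
              nrow(x$nodes), min(x$nodes$r), max(x$nodes$r)))
  k <- attr(x, "kappa")
  utils::str(x$nodes, give.attr = FALSE)
  invisible(x)
}

#' Export averaged coefficients alongside the orbit table
#'
#' @param coeffs an [coefficient_functions()] object.
#' @param path file path for the CSV.
#' @return the path, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  utils::write.csv(format(coeffs$nodes, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
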