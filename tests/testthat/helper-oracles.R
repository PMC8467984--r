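# Independent numerical oracles. Each one recomputes a quantity by a
# route deliberately different from the package implementation.

# Competition-case barred parameters by damped fixed-point iteration
# (package route: closed-form quadratic).
oracle_case2_effective <- function(a, b, c, f, s, B, tol = 1e-14) {
  b_bar <- b
  for (k in 1:10000) {
    f_bar <- f * b_bar / b
    a_bar <- a - s * c / f_bar
    b_new <- b - a_bar * B
    b_bar_next <- 0.5 * b_bar + 0.5 * b_new
    if (abs(b_bar_next - b_bar) < tol * b) {
      b_bar <- b_bar_next
      break
    }
    b_bar <- b_bar_next
  }
  f_bar <- f * b_bar / b
  a_bar <- a - s * c / f_bar
  c(a_bar = a_bar, b_bar = b_bar, f_bar = f_bar)
}

# Orbit average by a long fixed-step RK4 integration in log coordinates
# (package route: adaptive integrator with section-return event).
oracle_rk4_average <- function(eff, r, h_funs, n_periods = 200,
                               steps_per_period = 600) {
  Tq <- lvjump:::period_quadrature(eff, r)
  dt <- Tq / steps_per_period
  n <- n_periods * steps_per_period
  ext <- level_extents(eff, r)
  u <- log(ext[["x1_max"]]); v <- log(eff$a_bar / eff$b_bar)
  ab <- eff$a_bar; bb <- eff$b_bar; fb <- eff$f_bar; cc <- eff$c
  du <- function(u, v) ab - bb * exp(v)
  dv <- function(u, v) -cc + fb * exp(u)
  acc <- numeric(length(h_funs))
  for (k in seq_len(n)) {
    # accumulate (left endpoint; exact for periodic sampling over full
    # periods up to the RK4 trajectory error)
    x1 <- exp(u); x2 <- exp(v)
    acc <- acc + vapply(h_funs, function(h) h(x1, x2), numeric(1))
    k1u <- du(u, v);              k1v <- dv(u, v)
    k2u <- du(u + dt/2*k1u, v + dt/2*k1v)
    k2v <- dv(u + dt/2*k1u, v + dt/2*k1v)
    k3u <- du(u + dt/2*k2u, v + dt/2*k2v)
    k3v <- dv(u + dt/2*k2u, v + dt/2*k2v)
    k4u <- du(u + dt*k3u, v + dt*k3v)
    k4v <- dv(u + dt*k3u, v + dt*k3v)
    u <- u + dt/6*(k1u + 2*k2u + 2*k3u + k4u)
    v <- v + dt/6*(k1v + 2*k2v + 2*k3v + k4v)
  }
  acc / n
}

# Zero-flux stationary density by a marching finite-difference scheme on
# a uniform r grid (package route: quadrature of the exponent in log r).
oracle_fd_p0 <- function(coeffs, n = 12001L) {
  tab <- coeffs$table
  r <- seq(tab$r_lo, tab$r_max, length.out = n)
  h <- r[2] - r[1]
  g <- 2 * coeffs$A11bar(r) / coeffs$A21bar(r)
  # Crank-Nicolson recurrence for q' = g q, q = A21 p
  ratio <- (1 + h * g[-n] / 2) / (1 - h * g[-1] / 2)
  q <- c(1, cumprod(ratio))
  p <- q / coeffs$A21bar(r)
  p <- p / max(p)
  mass <- sum((p[-1] + p[-n]) / 2) * h + p[1] * r[1]  # + flat sub-grid part
  list(r = r, p0 = p / mass)
}

# Second-order correction by Crank-Nicolson marching of the
# once-integrated balance (package route: variation of constants with
# local-polynomial derivative fits). Forcing derivatives use wide-step
# central differences of coefficient values and of the FD p0.
oracle_fd_p2 <- function(coeffs, n = 12001L) {
  o <- oracle_fd_p0(coeffs, n)
  r <- o$r; p0 <- o$p0; n <- length(r); h <- r[2] - r[1]
  A11 <- coeffs$A11bar(r); A21 <- coeffs$A21bar(r)
  lp <- stats::splinefun(r, log(p0), method = "fmm")
  hd <- pmax(0.25 * r, 0.006)
  # symmetric 5-point stencils on a window shifted to stay in domain
  wide <- function(f, k) {
    lo <- r[1]; hi <- r[n]
    ctr <- pmin(pmax(r, lo + 2 * hd), hi - 2 * hd)
    z <- (r - ctr) / hd
    vm2 <- f(ctr - 2*hd); vm1 <- f(ctr - hd); v0 <- f(ctr)
    vp1 <- f(ctr + hd); vp2 <- f(ctr + 2*hd)
    # quartic through the 5 points, derivatives at z
    c0 <- v0
    c1 <- (8*(vp1 - vm1) - (vp2 - vm2)) / 12
    c2 <- (16*(vp1 + vm1) - (vp2 + vm2) - 30*v0) / 24
    c3 <- ((vp2 - vm2) - 2*(vp1 - vm1)) / 12
    c4 <- ((vp2 + vm2) - 4*(vp1 + vm1) + 6*v0) / 24
    d <- switch(k + 1L,
      c0 + c1*z + c2*z^2 + c3*z^3 + c4*z^4,
      c1 + 2*c2*z + 3*c3*z^2 + 4*c4*z^3,
      2*c2 + 6*c3*z + 12*c4*z^2,
      6*c3 + 24*c4*z)
    d / hd^k
  }
  L <- wide(function(x) lp(x), 1L)
  Lp <- wide(function(x) lp(x), 2L)
  Lpp <- wide(function(x) lp(x), 3L)
  f22 <- coeffs$A22bar(r); f31 <- coeffs$A31bar(r)
  f41 <- coeffs$A41bar(r)
  G <- coeffs$A12bar(r) -
    0.5 * (wide(coeffs$A22bar, 1L) + f22 * L) +
    (1/6) * (wide(coeffs$A31bar, 2L) + 2 * wide(coeffs$A31bar, 1L) * L +
               f31 * (Lp + L^2)) -
    (1/24) * (wide(coeffs$A41bar, 3L) + 3 * wide(coeffs$A41bar, 2L) * L +
                3 * wide(coeffs$A41bar, 1L) * (Lp + L^2) +
                f41 * (Lpp + 3 * L * Lp + L^3))
  G <- G * p0
  # march y' = alpha y + beta, alpha = (2A11 - A21')/A21, beta = 2G/A21
  A21p <- wide(coeffs$A21bar, 1L)
  alpha <- (2 * A11 - A21p) / A21
  beta <- 2 * G / A21
  y <- numeric(n)
  for (j in 1:(n - 1L)) {
    y[j + 1L] <- (y[j] * (1 + h * alpha[j] / 2) +
                    h * (beta[j] + beta[j + 1L]) / 2) /
      (1 - h * alpha[j + 1L] / 2)
  }
  mass_y <- sum((y[-1] + y[-n]) / 2) * h + y[1] * r[1]
  y <- y - mass_y * p0
  list(r = r, p0 = p0, p2 = y)
}

# O(eps^2) drift of the first integral by a central-difference generator
# applied to R (package route: closed-form U0).
oracle_generator_U0 <- function(eff, noise, x1, x2, h = 1e-6) {
  g <- g_corrections(eff, x1, x2)
  s <- eff$params$s
  corr1 <- x1 * (-(s / eff$f_bar) * (-eff$c + eff$f_bar * x1) + g$g1 +
                   noise$D1)
  corr2 <- x2 * (g$g2 + noise$D2)
  R <- function(a, b) first_integral(eff, a, b)
  # Richardson-extrapolated central differences: a plain second
  # difference at tiny h sits on the 1e-4 roundoff floor, far above the
  # agreement we are probing
  h <- 2e-3
  d1 <- function(f, h) (f(h) - f(-h)) / (2 * h)
  d2 <- function(f, h) (f(h) - 2 * f(0) + f(-h)) / h^2
  rich <- function(fd, f) (4 * fd(f, h / 2) - fd(f, h)) / 3
  dR1 <- rich(d1, function(e) R(x1 + e, x2))
  dR2 <- rich(d1, function(e) R(x1, x2 + e))
  d2R1 <- rich(d2, function(e) R(x1 + e, x2))
  d2R2 <- rich(d2, function(e) R(x1, x2 + e))
  dR1 * corr1 + dR2 * corr2 +
    0.5 * d2R1 * 2 * noise$D1 * x1^2 +
    0.5 * d2R2 * 2 * noise$D2 * x2^2
}
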