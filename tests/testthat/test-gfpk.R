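# build a synthetic coefficient object on top of a real table
synthetic_coeffs <- function(tab, A11f, A21f,
                             A12f = function(r) 0 * r,
                             A22f = function(r) 0 * r,
                             A31f = function(r) 0 * r,
                             A41f = function(r) 0 * r) {
  co <- coefficient_functions(tab$eff, lv_noise(D1 = 1e-3, D2 = 1e-3),
                              tab)
  co$A11bar <- A11f; co$A21bar <- A21f; co$A12bar <- A12f
  co$A22bar <- A22f; co$A31bar <- A31f; co$A41bar <- A41f
  co
}

test_that("constant coefficients give the exponential zero-flux density", {
  tab <- table_case1()
  k <- 3; sig <- 0.8
  co <- synthetic_coeffs(tab, function(r) rep(-k, length(r)),
                         function(r) rep(sig, length(r)))
  p0 <- solve_p0(co)
  ref <- (2 * k / sig) * exp(-2 * k * p0$r / sig)
  expect_lt(max(abs(p0$p0 / ref - 1)), 1e-4)
})

test_that("the first-order density has zero probability flux", {
  sol <- fit_case1_jump()$sol
  co <- sol$coeffs
  r <- sol$r
  # independent derivative of (A21 p0) via a mid-resolution spline
  f <- co$A21bar(r) * sol$pG
  sp <- stats::splinefun(sol$t, f)
  flux <- co$A11bar(r) * sol$pG - 0.5 * sp(sol$t, deriv = 1) / r
  expect_lt(max(abs(flux)), 1e-6 * max(abs(co$A11bar(r) * sol$pG)))
})

test_that("mass identities hold for all stationary densities", {
  sol <- fit_case1_jump()$sol
  mi <- function(y) lvjump:::mass_integral(sol$t, sol$r, y, sol$kappa)
  expect_equal(mi(sol$p0), 1, tolerance = 1e-8)
  expect_equal(mi(sol$pG), 1, tolerance = 1e-8)
  expect_equal(mi(sol$pR), 1, tolerance = 1e-8)
  expect_lt(abs(mi(sol$p2)), 1e-8)
  expect_true(all(sol$p0 >= 0))
  expect_lt(sol$neg_mass, 0.01)
  expect_equal(sol$kappa, 1, tolerance = 1e-3)
})

test_that("without jumps the perturbation solution is the Gaussian one", {
  fit <- lvsa(params_case1(), noise_zero_jump())
  expect_equal(fit$sol$p2, rep(0, length(fit$sol$r)))
  expect_equal(fit$sol$pR, fit$sol$pG, tolerance = 1e-12)
})

test_that("first-order density matches an independent finite-difference solve", {
  for (fitcase in list(fit_case1_jump(),
                       lvsa(params_case2(),
                            noise_jump(lambda = 0.2, m = 0.04)))) {
    co <- fitcase$coeffs
    o <- oracle_fd_p0(co)
    mine <- stationary_density(fitcase$sol, o$r, "gaussian")
    keep <- o$p0 > 1e-10 * max(o$p0)
    expect_lt(max(abs(mine[keep] / o$p0[keep] - 1)), 1e-4)
  }
})

test_that("second-order correction matches an independent finite-difference solve", {
  for (fitcase in list(fit_case1_jump(),
                       lvsa(params_case2(),
                            noise_jump(lambda = 0.2, m = 0.04)))) {
    o <- oracle_fd_p2(fitcase$coeffs)
    mine <- stationary_density(fitcase$sol, o$r, "correction")
    rel <- sqrt(sum((mine - o$p2)^2) / sum(o$p2^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("the jump correction raises the density peak", {
  sol <- fit_case1_jump()$sol
  expect_gt(max(sol$pR), max(sol$pG))
})

test_that("the solution is converged in the level-grid resolution", {
  fit1 <- fit_case1_jump()
  fit2 <- lvsa(params_case1(), noise_jump(),
               lvsa_control(n_levels = 201L))
  pR2 <- stationary_density(fit2$sol, fit1$sol$r, "perturbation")
  l1 <- lvjump:::mass_integral(fit1$sol$t, fit1$sol$r,
                               abs(pR2 - fit1$sol$pR), fit1$sol$kappa)
  expect_lt(l1, 1e-4)
})

test_that("the perturbation solution approaches the Gaussian one as jumps densify", {
  # lambda up at fixed intensity lambda*m: Poisson forcing -> Gaussian
  e <- eff_case1()
  tab <- table_case1()
  l1_dist <- vapply(c(0.05, 0.1, 0.2, 0.5, 1, 2), function(lam) {
    co <- coefficient_functions(e, noise_jump(lam, 0.008 / lam), tab)
    sol <- assemble_stationary(co)
    lvjump:::mass_integral(sol$t, sol$r, abs(sol$pR - sol$pG),
                           sol$kappa)
  }, numeric(1))
  expect_true(all(diff(l1_dist) < 0))
})
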