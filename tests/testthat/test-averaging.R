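test_that("jump-response coefficients follow the Taylor factors", {
  e <- eff_case1()
  jp <- jump_polynomials(e, e$x1_star, e$x2_star)
  expect_equal(jp$A11, 0, tolerance = 1e-14)
  expect_equal(jp$A21, 0, tolerance = 1e-14)
  expect_equal(jp$A12, e$c / 2)
  expect_equal(jp$A22, e$a_bar / 2)
  jp2 <- jump_polynomials(e, 1.7, 0.4)
  expect_equal(jp2$A13 / jp2$A12, 1 / 3)
  expect_equal(jp2$A14 / jp2$A12, 1 / 12)
  expect_equal(jp2$A23 / jp2$A22, 1 / 3)
  expect_equal(jp2$A24 / jp2$A22, 1 / 12)
  jp3 <- jump_polynomials(e, 1.2, 0.8)
  expect_equal(jp3$A11, 0.475 * 1.2 - 0.5, tolerance = 1e-14)
})

test_that("the first-integral drift correction matches its special cases", {
  # everything off: no drift correction anywhere
  e0 <- effective_params(lv_params("saturation", 1, 1, 0.5, 0.5))
  n0 <- lv_noise()
  expect_equal(drift_correction_U0(e0, n0, 1.3, 0.7), 0,
               tolerance = 1e-14)
  # only Gaussian noise: at equilibrium just the Ito-correction constants
  nD <- lv_noise(D1 = 0.003, D2 = 0.001)
  u <- drift_correction_U0(e0, nD, e0$x1_star, e0$x2_star)
  expect_equal(u, e0$c * 0.003 + e0$a_bar * 0.001, tolerance = 1e-14)
})

test_that("the drift correction equals the finite-difference generator", {
  set.seed(31)
  for (p in list(params_case1(), params_case2())) {
    e <- effective_params(p)
    no <- lv_noise(D1 = 0.002, D2 = 0.0007, lambda1 = 0.3,
                   lambda2 = 0.1, m1 = 0.02, m2 = 0.05)
    x1 <- exp(runif(20, -1, 1)) * e$x1_star
    x2 <- exp(runif(20, -1, 1)) * e$x2_star
    u <- drift_correction_U0(e, no, x1, x2)
    o <- oracle_generator_U0(e, no, x1, x2)
    expect_lt(max(abs(u - o) / (1e-3 + abs(u))), 1e-8)
  }
})

test_that("without jumps every jump-specific coefficient vanishes", {
  e <- eff_case1()
  co <- coefficient_functions(e, noise_zero_jump(), table_case1())
  r <- c(0.01, 0.3, 1.5)
  expect_equal(co$A12bar(r), rep(0, 3))
  expect_equal(co$A22bar(r), rep(0, 3))
  expect_equal(co$A31bar(r), rep(0, 3))
  expect_equal(co$A41bar(r), rep(0, 3))
  expect_true(all(co$A21bar(r) > 0))
})

test_that("diffusion-type coefficients vanish at the equilibrium level", {
  e <- eff_case1()
  co <- coefficient_functions(e, noise_jump(), table_case1())
  expect_lt(co$A21bar(1e-8), 1e-8)
  expect_lt(co$A41bar(1e-8), 1e-8)
  expect_gt(co$A21bar(0.5), 0)
  expect_gt(co$A41bar(0.5), 0)
})

test_that("drift and diffusion depend on the noise only through the total intensities", {
  e <- eff_case1()
  tab <- table_case1()
  # trade Gaussian for Poisson intensity keeping 2D + lambda m fixed
  nA <- lv_noise(D1 = 0.004, D2 = 0.001, lambda1 = 0.2, lambda2 = 0.5,
                 m1 = 0.01, m2 = 0.012)
  nB <- lv_noise(D1 = 0.0005, D2 = 0.003, lambda1 = 0.5, lambda2 = 0.2,
                 m1 = (2 * 0.004 + 0.2 * 0.01 - 2 * 0.0005) / 0.5,
                 m2 = (2 * 0.001 + 0.5 * 0.012 - 2 * 0.003) / 0.2)
  cA <- coefficient_functions(e, nA, tab)
  cB <- coefficient_functions(e, nB, tab)
  r <- c(0.05, 0.4, 1.2)
  expect_equal(cA$A21bar(r), cB$A21bar(r), tolerance = 1e-12)
  # A11bar is invariant too: the Ito-correction D-terms and the
  # second-order jump drift combine into (2D_i + lambda_i m_i)/2 factors
  expect_equal(cA$A11bar(r), cB$A11bar(r), tolerance = 1e-12)
})

test_that("jump coefficients scale linearly in rate and quadratically in magnitude", {
  e <- eff_case1()
  tab <- table_case1()
  base <- lv_noise(two_D1 = 0.001, two_D2 = 0.001, lambda1 = 0.1,
                   lambda2 = 0.1, m1 = 0.05, m2 = 0.05)
  dblL <- lv_noise(two_D1 = 0.001, two_D2 = 0.001, lambda1 = 0.2,
                   lambda2 = 0.2, m1 = 0.05, m2 = 0.05)
  dblM <- lv_noise(two_D1 = 0.001, two_D2 = 0.001, lambda1 = 0.1,
                   lambda2 = 0.1, m1 = 0.1, m2 = 0.1)
  cb <- coefficient_functions(e, base, tab)
  cl <- coefficient_functions(e, dblL, tab)
  cm <- coefficient_functions(e, dblM, tab)
  r <- c(0.1, 0.8)
  for (nm in c("A12bar", "A22bar", "A31bar", "A41bar")) {
    expect_equal(cl[[nm]](r), 2 * cb[[nm]](r), tolerance = 1e-12)
    expect_equal(cm[[nm]](r), 4 * cb[[nm]](r), tolerance = 1e-12)
  }
})

test_that("averaged coefficients agree with long fixed-step orbit averaging", {
  e <- eff_case1()
  tab <- table_case1()
  no <- noise_jump()
  co <- coefficient_functions(e, no, tab)
  fb <- e$f_bar; bb <- e$b_bar; cc <- e$c; ab <- e$a_bar
  s <- e$params$s
  levels <- c(0.02, 0.1, 0.35, 0.9, 1.8)
  for (r in levels) {
    h_funs <- list(
      U0 = function(x1, x2) drift_correction_U0(e, no, x1, x2),
      A12 = function(x1, x2) fb * x1 / 2,
      A22 = function(x1, x2) bb * x2 / 2,
      A14 = function(x1, x2) fb * x1 / 24,
      A24 = function(x1, x2) bb * x2 / 24,
      A11sq = function(x1, x2) (fb * x1 - cc)^2,
      A21sq = function(x1, x2) (bb * x2 - ab)^2,
      mix1 = function(x1, x2) (fb * x1 / 2)^2 +
        2 * (fb * x1 - cc) * fb * x1 / 6,
      mix2 = function(x1, x2) (bb * x2 / 2)^2 +
        2 * (bb * x2 - ab) * bb * x2 / 6,
      tri1 = function(x1, x2) 3 * (fb * x1 - cc)^2 * fb * x1 / 2,
      tri2 = function(x1, x2) 3 * (bb * x2 - ab)^2 * bb * x2 / 2,
      qu1 = function(x1, x2) (fb * x1 - cc)^4,
      qu2 = function(x1, x2) (bb * x2 - ab)^4)
    av <- oracle_rk4_average(e, r, h_funs, n_periods = 200,
                             steps_per_period = 500)
    q1 <- 3 * no$m1^2 * no$lambda1
    q2 <- 3 * no$m2^2 * no$lambda2
    g1 <- 2 * no$D1 + no$lambda1 * no$m1
    g2 <- 2 * no$D2 + no$lambda2 * no$m2
    expect_equal(co$A11bar(r),
                 av[["U0"]] + no$lambda1 * no$m1 * av[["A12"]] +
                   no$lambda2 * no$m2 * av[["A22"]],
                 tolerance = 5e-3)
    expect_equal(co$A12bar(r), q1 * av[["A14"]] + q2 * av[["A24"]],
                 tolerance = 5e-3)
    expect_equal(co$A21bar(r), av[["A11sq"]] * g1 + av[["A21sq"]] * g2,
                 tolerance = 5e-3)
    expect_equal(co$A22bar(r), q1 * av[["mix1"]] + q2 * av[["mix2"]],
                 tolerance = 5e-3)
    expect_equal(co$A31bar(r), q1 * av[["tri1"]] + q2 * av[["tri2"]],
                 tolerance = 5e-3)
    expect_equal(co$A41bar(r), q1 * av[["qu1"]] + q2 * av[["qu2"]],
                 tolerance = 5e-3)
  }
})
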