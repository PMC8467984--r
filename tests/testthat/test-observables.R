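test_that("joint density integrates to one over the positive quadrant", {
  fit <- fit_case1_jump()
  r_cut <- level_mass_cut(fit$sol)
  ext <- level_extents(fit$eff, r_cut)
  x1 <- seq(ext[["x1_min"]], ext[["x1_max"]], length.out = 220L)
  x2 <- seq(ext[["x2_min"]], ext[["x2_max"]], length.out = 220L)
  z <- outer(x1, x2, function(a, b) joint_pdf(fit, NULL, a, b))
  mass <- lvjump:::trapz(x1, apply(z, 1, function(col)
    lvjump:::trapz(x2, col)))
  expect_equal(mass, 1, tolerance = 5e-3)
})

test_that("the joint density is uniform in orbit time along a level curve", {
  fit <- fit_case1_jump()
  r <- 0.4
  ext <- level_extents(fit$eff, r)
  # points on the level curve across both predator branches
  x1 <- seq(ext[["x1_min"]] * 1.001, ext[["x1_max"]] * 0.999,
            length.out = 15L)
  rho <- r - lvjump:::phi1(fit$eff, x1)
  for (lower in c(TRUE, FALSE)) {
    x2 <- vapply(rho, function(v)
      lvjump:::phi_invert(fit$eff$b_bar, fit$eff$a_bar, v, lower),
      numeric(1))
    val <- joint_pdf(fit, NULL, x1, x2) * x1 * x2
    expect_lt(diff(range(val)) / mean(val), 1e-6)
  }
})

test_that("marginal densities carry unit mass on their support", {
  fit <- fit_case1_jump()
  for (ax in c("prey", "predator")) {
    m <- marginal_pdf(fit, NULL, ax, which = "perturbation",
                      rel.tol = 1e-7)
    expect_gt(lvjump:::trapz(m$x, m$density), 0.99)
    expect_lt(lvjump:::trapz(m$x, m$density), 1.01)
    expect_gt(min(m$density), -1e-6)
  }
})

test_that("without jumps both marginal variants coincide", {
  fit <- lvsa(params_case1(), noise_zero_jump())
  for (ax in c("prey", "predator")) {
    mp <- marginal_pdf(fit, NULL, ax, which = "perturbation",
                       rel.tol = 1e-7)
    mg <- marginal_pdf(fit, NULL, ax, mp$x, which = "gaussian",
                       rel.tol = 1e-7)
    expect_equal(mp$density, mg$density, tolerance = 1e-9)
    expect_lt(l2_error(mp, mg), 1e-10)
  }
})

test_that("sparse jumps raise the marginal maxima above the Gaussian ones", {
  fit <- fit_case1_jump()
  for (ax in c("prey", "predator")) {
    mp <- marginal_pdf(fit, NULL, ax, which = "perturbation",
                       rel.tol = 1e-6)
    mg <- marginal_pdf(fit, NULL, ax, mp$x, which = "gaussian",
                       rel.tol = 1e-6)
    expect_gt(max(mp$density), max(mg$density))
  }
})

test_that("stationary means equal the equilibrium coordinates", {
  fit <- fit_case1_jump()
  mom <- stationary_moments(fit)
  expect_equal(mom$mean_x1, fit$eff$x1_star, tolerance = 1e-8)
  expect_equal(mom$mean_x2, fit$eff$x2_star, tolerance = 1e-8)
  expect_gt(mom$var_x1, 0)
  expect_equal(mom$relfluct_x1, sqrt(mom$var_x1) / mom$mean_x1)
  expect_equal(mom$var_over_mean_x1, mom$var_x1 / mom$mean_x1)
})

test_that("moments via marginal quadrature agree with the level-grid route", {
  fit <- fit_case1_jump()
  mom <- stationary_moments(fit)
  m <- marginal_pdf(fit, NULL, "prey", which = "perturbation",
                    rel.tol = 1e-7)
  mean_marg <- lvjump:::trapz(m$x, m$x * m$density)
  var_marg <- lvjump:::trapz(m$x, (m$x - mean_marg)^2 * m$density)
  expect_equal(mean_marg, mom$mean_x1, tolerance = 1e-3)
  expect_equal(var_marg, mom$var_x1, tolerance = 5e-3)
})

test_that("the L2 metric is a discrepancy: zero on identical inputs", {
  fit <- fit_case1_jump()
  m <- marginal_pdf(fit, NULL, "prey", which = "perturbation",
                    rel.tol = 1e-6)
  expect_identical(l2_error(m, m), 0)
  m2 <- marginal_pdf(fit, NULL, "predator", which = "perturbation",
                     rel.tol = 1e-6)
  expect_error(l2_error(m, m2), "axes")
})

test_that("direct and differenced L2 computations agree where both resolve", {
  fit <- fit_case1_jump()
  direct <- local({
    mp <- marginal_pdf(fit, NULL, "prey", which = "perturbation",
                       rel.tol = 1e-9)
    mg <- marginal_pdf(fit, NULL, "prey", mp$x, which = "gaussian",
                       rel.tol = 1e-9)
    l2_error(mp, mg)
  })
  viadiff <- l2_perturbation_vs_gaussian(fit, NULL, "prey")
  expect_equal(direct, viadiff, tolerance = 1e-3)
})
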