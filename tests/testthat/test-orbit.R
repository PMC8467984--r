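test_that("first integral is zero at equilibrium and positive elsewhere", {
  e <- eff_case1()
  expect_equal(first_integral(e, e$x1_star, e$x2_star), 0,
               tolerance = 1e-14)
  # closed form at a reference state (A = 0 variant)
  e0 <- effective_params(lv_params("saturation", 1, 1, 0.5, 0.5, s = 0.1))
  r <- first_integral(e0, 1.2, 1.2)
  expect_equal(r,
               0.5 * 1.2 - 0.5 - 0.5 * log(0.5 * 1.2 / 0.5) +
                 1 * 1.2 - 0.9 - 0.9 * log(1.2 / 0.9),
               tolerance = 1e-14)
  set.seed(7)
  x1 <- exp(runif(200, -2, 2)) * e$x1_star
  x2 <- exp(runif(200, -2, 2)) * e$x2_star
  expect_true(all(first_integral(e, x1, x2) >= 0))
  expect_error(first_integral(e, -1, 1), "positive")
})

test_that("level extents solve the potential equations and shrink like sqrt(r)", {
  e <- eff_case1()
  ext <- level_extents(e, 0.5)
  expect_lt(ext[["x1_min"]], e$x1_star)
  expect_gt(ext[["x1_max"]], e$x1_star)
  expect_equal(lvjump:::phi1(e, ext[["x1_min"]]), 0.5, tolerance = 1e-10)
  expect_equal(lvjump:::phi1(e, ext[["x1_max"]]), 0.5, tolerance = 1e-10)
  expect_equal(lvjump:::phi2(e, ext[["x2_min"]]), 0.5, tolerance = 1e-10)
  expect_equal(lvjump:::phi2(e, ext[["x2_max"]]), 0.5, tolerance = 1e-10)
  # harmonic width: x1 half-width ~ sqrt(2 c r)/f_bar as r -> 0
  for (r in c(1e-6, 1e-8)) {
    ex <- level_extents(e, r)
    w <- (ex[["x1_max"]] - ex[["x1_min"]]) / 2
    expect_equal(w, sqrt(2 * e$c * r) / e$f_bar, tolerance = 1e-2)
  }
  expect_error(level_extents(e, -0.1), "positive")
})

test_that("orbit averages honour the classical mean-value identities", {
  e <- eff_case1()
  for (r in c(0.01, 0.2, 1.0)) {
    tr <- trace_orbit(e, r, list(one = function(x1, x2) 1,
                                 x1 = function(x1, x2) x1,
                                 x2 = function(x1, x2) x2))
    expect_equal(tr$avg[["one"]], 1, tolerance = 1e-9)
    expect_equal(tr$avg[["x1"]], e$x1_star, tolerance = 1e-8)
    expect_equal(tr$avg[["x2"]], e$x2_star, tolerance = 1e-8)
  }
})

test_that("the quasi-period approaches the harmonic limit as r -> 0", {
  e <- eff_case1()
  Th <- 2 * pi / sqrt(e$a_bar * e$c)
  expect_equal(harmonic_period(e), Th)
  expect_equal(Th, 9.3939, tolerance = 1e-4)
  tr <- trace_orbit(e, 1e-6)
  expect_equal(tr$T / Th, 1, tolerance = 1e-3)
})

test_that("the first integral is conserved along a traced orbit", {
  e <- eff_case1()
  r0 <- 0.8
  ext <- level_extents(e, r0)
  deriv <- function(t, y, p) {
    list(c(e$a_bar - e$b_bar * exp(y[2]), -e$c + e$f_bar * exp(y[1])))
  }
  Tq <- lvjump:::period_quadrature(e, r0)
  out <- deSolve::lsoda(c(log(ext[["x1_max"]]), log(e$x2_star)),
                        seq(0, Tq, length.out = 200), deriv,
                        rtol = 1e-10, atol = 1e-10)
  rs <- first_integral(e, exp(out[, 2]), exp(out[, 3]))
  expect_lt(max(abs(rs - r0)), 1e-8 * (1 + r0))
})

test_that("time-integrated and quadrature periods agree", {
  e <- eff_case1()
  for (r in exp(seq(log(1e-3), log(2), length.out = 10))) {
    Tt <- trace_orbit(e, r)$T
    Tq <- lvjump:::period_quadrature(e, r)
    expect_equal(Tt / Tq, 1, tolerance = 1e-6)
  }
})

test_that("the orbit table interpolates its own nodes and is monotone in T", {
  tab <- table_case1()
  e <- tab$eff
  expect_true(all(diff(tab$r) > 0))
  expect_true(all(diff(tab$T) > 0))          # period grows with amplitude
  expect_lt(max(abs(tab$avg[, "x1"] / e$x1_star - 1)), 1e-8)
  expect_lt(max(abs(tab$avg[, "x2"] / e$x2_star - 1)), 1e-8)
  i <- c(3, 47, 99)
  expect_equal(lvjump:::orbit_column(tab, "T", tab$r[i]), tab$T[i],
               tolerance = 1e-12)
  expect_equal(lvjump:::orbit_column(tab, "x1p2", tab$r[i]),
               unname(tab$avg[i, "x1p2"]), tolerance = 1e-12)
  # below the grid floor: analytic limits
  expect_equal(lvjump:::orbit_column(tab, "T", 0), harmonic_period(e))
  expect_equal(lvjump:::orbit_column(tab, "x1", 0), e$x1_star)
})

test_that("orbit tables serialize to CSV and re-load bit-faithfully", {
  tab <- table_case1()
  path <- tempfile(fileext = ".csv")
  write_orbit_table(tab, path)
  df <- utils::read.csv(path)
  expect_identical(names(df)[1:2], c("r", "T"))
  expect_true(all(paste0("avg_", colnames(tab$avg)) %in% names(df)))
  expect_equal(df$r, tab$r, tolerance = 1e-15)
  expect_equal(df$T, tab$T, tolerance = 1e-15)
  expect_equal(df$avg_U0a, unname(tab$avg[, "U0a"]), tolerance = 1e-15)
})
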