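# Shared parameter sets and lazily-built heavy objects.

params_case1 <- function(A = 0.05, s = 0.1)
  lv_params("saturation", a = 1, b = 1, c = 0.5, f = 0.5, s = s, A = A)

params_case2 <- function(B = 0.05, s = 0.08)
  lv_params("competition", a = 1, b = 1, c = 0.5, f = 0.5, s = s, B = B)

# sparse-jump noise used in the validation studies (intensity 0.008)
noise_jump <- function(lambda = 0.1, m = 0.08)
  lv_noise(two_D1 = 0.001, two_D2 = 0.001, lambda1 = lambda,
           lambda2 = lambda, m1 = m, m2 = m)

noise_zero_jump <- function()
  lv_noise(two_D1 = 0.001, two_D2 = 0.001)

# memoized heavy fixtures shared across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

eff_case1 <- function() cached("eff1", effective_params(params_case1()))

table_case1 <- function()
  cached("tab1", build_orbit_table(eff_case1(), r_max = 2.9,
                                   n_levels = 101))

fit_case1_jump <- function()
  cached("fit1j", lvsa(params_case1(), noise_jump()))

random_valid_params <- function(rng_n = 1L) {
  # one random strictly valid parameter set per call
  case <- sample(c("saturation", "competition"), 1L)
  a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 2)
  c <- runif(1, 0.3, 1); f <- runif(1, 0.5, 1.5)
  s <- runif(1, 0, 0.2)
  if (case == "saturation") {
    A <- runif(1, 0, min(0.3, 0.8 * f / c))
    lv_params("saturation", a, b, c, f, s = s, A = A)
  } else {
    B <- runif(1, 0, 0.3)
    # keep a_bar positive
    p <- try(lv_params("competition", a, b, c, f, s = s, B = B),
             silent = TRUE)
    if (inherits(p, "try-error")) params_case2() else p
  }
}
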