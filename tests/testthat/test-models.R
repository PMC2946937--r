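# independent oracle: N(t) by adaptive quadrature of the net rate
quad_diversity <- function(spec, t) {
  net <- function(s) {
    r <- rates_at(spec, s)
    r$speciation - r$extinction
  }
  spec$N0 * exp(-stats::integrate(net, 0, t, rel.tol = 1e-12)$value)
}

test_that("model constructors enforce the per-model parameter sets", {
  tab <- diversification_models()
  expect_equal(tab$k,
               c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 1L, 2L))
  expect_error(diversification_model("M1", lambda0 = 1, N0 = 10),
               "takes parameters")
  expect_error(diversification_model("M3", lambda0 = 1, mu0 = 2, N0 = 10),
               "mu0 <= lambda0")
  expect_error(diversification_model("M4c", lambda0 = 1, alpha = 0,
                                     epsilon = 1.2, N0 = 10), "epsilon")
  expect_error(diversification_model("M5", lambda0 = -1, N0 = 10), ">= 0")
})

test_that("rates_at reproduces the per-model rate functions", {
  m6 <- diversification_model("M6", lambda0 = 6, alpha = 0.25, N0 = 100)
  r <- rates_at(m6, 0)
  expect_equal(r$speciation, 6)
  expect_equal(r$extinction, 0)
  expect_equal(rates_at(m6, 2)$speciation, 6 * exp(0.5))

  m3 <- diversification_model("M3", lambda0 = 1, mu0 = 0.5, N0 = 100)
  r3 <- rates_at(m3, c(0, 1, 7))
  expect_equal(r3$speciation, rep(1, 3))
  expect_equal(r3$extinction, rep(0.5, 3))

  # saturated models: both rates equal the turnover rate
  m2 <- diversification_model("M2", tau0 = 2, gamma = 0.3, N0 = 100)
  r2 <- rates_at(m2, 1.5)
  expect_equal(r2$speciation, r2$extinction)
  expect_equal(r2$speciation, 2 * exp(0.45))

  expect_error(rates_at(m3, -1), "t must be")
})

test_that("nested parameterizations give identical rates", {
  ts <- c(0, 0.5, 2, 10)
  pairs <- list(
    list(diversification_model("M2", tau0 = 3, gamma = 0, N0 = 50),
         diversification_model("M1", tau0 = 3, N0 = 50)),
    list(diversification_model("M3", lambda0 = 2, mu0 = 0, N0 = 50),
         diversification_model("M5", lambda0 = 2, N0 = 50)),
    list(diversification_model("M4a", lambda0 = 2, alpha = 0, mu0 = 1,
                               N0 = 50),
         diversification_model("M3", lambda0 = 2, mu0 = 1, N0 = 50)),
    list(diversification_model("M4c", lambda0 = 2, alpha = 0.4, epsilon = 0,
                               N0 = 50),
         diversification_model("M6", lambda0 = 2, alpha = 0.4, N0 = 50)),
    list(diversification_model("M6", lambda0 = 2, alpha = 0, N0 = 50),
         diversification_model("M5", lambda0 = 2, N0 = 50))
  )
  for (p in pairs) {
    expect_equal(rates_at(p[[1]], ts), rates_at(p[[2]], ts))
    expect_equal(expected_diversity(p[[1]], ts),
                 expected_diversity(p[[2]], ts))
  }
})

test_that("expected diversity matches closed-form arithmetic", {
  m5 <- diversification_model("M5", lambda0 = log(2), N0 = 100)
  expect_equal(expected_diversity(m5, 1), 50)
  m1 <- diversification_model("M1", tau0 = 7, N0 = 100)
  expect_equal(expected_diversity(m1, c(0, 3, 99)), rep(100, 3))
})

test_that("closed-form N(t) agrees with quadrature on random draws", {
  set.seed(31)
  for (i in 1:20) {
    model <- sample(c("M3", "M4a", "M4b", "M4c", "M4d", "M5", "M6"), 1)
    lam <- runif(1, 0.2, 3)
    pars <- switch(model,
      M3  = list(lambda0 = lam, mu0 = runif(1, 0, lam)),
      M4a = list(lambda0 = lam, alpha = runif(1, -0.5, 0.5),
                 mu0 = runif(1, 0, 0.2)),
      M4b = list(lambda0 = lam, mu0 = runif(1, 0, 0.3),
                 beta = runif(1, -0.5, 0.5)),
      M4c = list(lambda0 = lam, alpha = runif(1, -0.5, 0.5),
                 epsilon = runif(1)),
      M4d = list(lambda0 = lam, alpha = runif(1, -0.5, 0.5),
                 mu0 = runif(1, 0, 0.3), beta = runif(1, -0.5, 0.5)),
      M5  = list(lambda0 = lam),
      M6  = list(lambda0 = lam, alpha = runif(1, -0.5, 0.5)))
    spec <- do.call(diversification_model,
                    c(list(model = model), pars, list(N0 = 100)))
    t <- runif(1, 0.1, 3)
    expect_equal(expected_diversity(spec, t), quad_diversity(spec, t),
                 tolerance = 1e-8)
  }
})

test_that("near-zero variation coefficients use the constant-rate limit", {
  tiny <- diversification_model("M4a", lambda0 = 1, alpha = 1e-12,
                                mu0 = 0.5, N0 = 100)
  const <- diversification_model("M3", lambda0 = 1, mu0 = 0.5, N0 = 100)
  expect_equal(expected_diversity(tiny, 5), expected_diversity(const, 5))
  expect_true(is.finite(expected_diversity(tiny, 5)))
})

test_that("N(0) = N0 and N is nonincreasing backwards when lambda >= mu", {
  set.seed(32)
  specs <- list(
    diversification_model("M1", tau0 = 1, N0 = 80),
    diversification_model("M3", lambda0 = 1, mu0 = 0.6, N0 = 80),
    diversification_model("M4d", lambda0 = 1, alpha = 0.3, mu0 = 0.5,
                          beta = 0.1, N0 = 80),
    diversification_model("M6", lambda0 = 1, alpha = 0.4, N0 = 80)
  )
  ts <- seq(0, 4, length.out = 60)
  for (s in specs) {
    expect_equal(expected_diversity(s, 0), 80)
    if (validate_constraint(s, max(ts)))
      expect_true(all(diff(expected_diversity(s, ts)) <= 1e-12))
  }
})

test_that("the speciation >= extinction check catches crossings", {
  # lambda decays into the past and dips below mu at t ~ 1.39
  bad <- diversification_model("M4a", lambda0 = 1, alpha = -0.5, mu0 = 0.5,
                               N0 = 100)
  expect_false(validate_constraint(bad, 2))
  expect_true(validate_constraint(bad, 1))
  # no-extinction models always pass
  m6 <- diversification_model("M6", lambda0 = 3, alpha = -2, N0 = 100)
  expect_true(validate_constraint(m6, 50))
  # equality is allowed
  m3 <- diversification_model("M3", lambda0 = 1, mu0 = 1, N0 = 100)
  expect_true(validate_constraint(m3, 10))
  # the grid path agrees with the endpoint path
  expect_false(validate_constraint(bad, 2, grid_points = 1000))
})
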