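# Oracles for the likelihood kernel: hand evaluation on toy trees, the
# closed-form Hey path, quadrature refinements, and invariances.

test_that("two-term hand evaluation on a 3-tip tree", {
  ct <- coalescent_times(toy3())
  # kappa * C(2,2 pairs) * tau0/N0 = 2 * 1 * 50/100 = 1, g_2 = 1
  m <- diversification_model("M1", tau0 = 50, N0 = 100)
  expect_equal(log_likelihood(m, ct), log(1) - 1)
  expect_equal(log_likelihood_hey(50, 100, ct), log(1) - 1)
  # rate 2, g_2 = 0.5 -> log 2 - 1
  ct2 <- as_coalescent_times(c(1.5, 1))
  expect_equal(log_likelihood_hey(100, 100, ct2), log(2) - 1)
})

test_that("Hey closed form equals the generic path under M1", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    ct <- coalescent_times(random_ultrametric(n))
    tau0 <- runif(1, 0.1, 5)
    N0 <- n + sample(0:50, 1)
    m <- diversification_model("M1", tau0 = tau0, N0 = N0)
    expect_equal(log_likelihood(m, ct), log_likelihood_hey(tau0, N0, ct),
                 tolerance = 1e-10)
  }
})

test_that("the Hey likelihood depends only on tau0/N0", {
  set.seed(42)
  ct <- coalescent_times(random_ultrametric(15))
  expect_equal(log_likelihood_hey(1.3, 40, ct),
               log_likelihood_hey(2.6, 80, ct))
})

test_that("nested-model likelihood identities hold to machine tolerance", {
  set.seed(43)
  ct <- coalescent_times(random_ultrametric(20))
  N0 <- 60
  pairs <- list(
    list(diversification_model("M2", tau0 = 2, gamma = 0, N0 = N0),
         diversification_model("M1", tau0 = 2, N0 = N0)),
    list(diversification_model("M3", lambda0 = 1.5, mu0 = 0, N0 = N0),
         diversification_model("M5", lambda0 = 1.5, N0 = N0)),
    list(diversification_model("M4c", lambda0 = 1.2, alpha = 0.3,
                               epsilon = 0, N0 = N0),
         diversification_model("M6", lambda0 = 1.2, alpha = 0.3, N0 = N0)),
    list(diversification_model("M6", lambda0 = 1.5, alpha = 0, N0 = N0),
         diversification_model("M5", lambda0 = 1.5, N0 = N0)),
    list(diversification_model("M4d", lambda0 = 1.2, alpha = 0.3,
                               mu0 = 0.6, beta = 0.3, N0 = N0),
         diversification_model("M4c", lambda0 = 1.2, alpha = 0.3,
                               epsilon = 0.5, N0 = N0))
  )
  for (p in pairs)
    expect_equal(log_likelihood(p[[1]], ct), log_likelihood(p[[2]], ct),
                 tolerance = 1e-9)
})

test_that("quadrature models agree with a brute-force trapezoid oracle", {
  set.seed(44)
  ct <- coalescent_times(random_ultrametric(20))
  specs <- list(
    diversification_model("M4a", lambda0 = 1, alpha = 0.4, mu0 = 0.3,
                          N0 = 40),
    diversification_model("M4b", lambda0 = 1, mu0 = 0.2, beta = 0.5,
                          N0 = 40),
    diversification_model("M4d", lambda0 = 1, alpha = 0.3, mu0 = 0.3,
                          beta = 0.1, N0 = 40)
  )
  trapz_logL <- function(spec, ct, kappa = 2, pts = 20000) {
    d <- ct$node_depths
    f <- function(s) {
      r <- rates_at(spec, s)$speciation
      r / expected_diversity(spec, s)
    }
    total <- 0
    for (j in 2:(ct$n - 1)) {
      a <- d[j]; b <- d[j - 1]
      s <- seq(a, b, length.out = pts)
      lam_int <- sum((f(s)[-1] + f(s)[-pts]) / 2) * (b - a) / (pts - 1)
      pairs <- j * (j - 1) / 2
      total <- total + log(kappa * pairs * f(b)) - kappa * pairs * lam_int
    }
    total
  }
  for (spec in specs)
    expect_equal(log_likelihood(spec, ct), trapz_logL(spec, ct),
                 tolerance = 1e-6)
})

test_that("closed-form cumulative rates match adaptive quadrature", {
  set.seed(45)
  quad <- function(spec, j, a, b, kappa = 2) {
    f <- function(s) rates_at(spec, s)$speciation /
      expected_diversity(spec, s)
    kappa * j * (j - 1) / 2 *
      stats::integrate(f, a, b, rel.tol = 1e-12)$value
  }
  specs <- list(
    diversification_model("M1", tau0 = 2, N0 = 70),
    diversification_model("M2", tau0 = 2, gamma = 0.4, N0 = 70),
    diversification_model("M3", lambda0 = 1.5, mu0 = 0.7, N0 = 70),
    diversification_model("M4c", lambda0 = 1.2, alpha = 0.5, epsilon = 0.6,
                          N0 = 70),
    diversification_model("M5", lambda0 = 0.8, N0 = 70),
    diversification_model("M6", lambda0 = 0.9, alpha = -0.3, N0 = 70)
  )
  for (spec in specs) {
    for (i in 1:5) {
      a <- runif(1, 0, 2); b <- a + runif(1, 0, 2)
      j <- sample(2:10, 1)
      expect_equal(cumulative_rate(spec, j, a, b),
                   quad(spec, j, a, b), tolerance = 1e-8)
    }
  }
})

test_that("cumulative rates are additive and vanish on empty intervals", {
  set.seed(46)
  m <- diversification_model("M6", lambda0 = 1.1, alpha = 0.25, N0 = 50)
  expect_equal(cumulative_rate(m, 4, 1, 1), 0)
  expect_equal(cumulative_rate(m, 4, 0, 2),
               cumulative_rate(m, 4, 0, 1) + cumulative_rate(m, 4, 1, 2),
               tolerance = 1e-10)
  # M1 closed form and the M5 textbook integral
  m1 <- diversification_model("M1", tau0 = 3, N0 = 100)
  expect_equal(cumulative_rate(m1, 5, 0.5, 2),
               2 * 10 * 3 / 100 * 1.5)
  m5 <- diversification_model("M5", lambda0 = 0.7, N0 = 100)
  expect_equal(cumulative_rate(m5, 2, 0, 2), (2 / 100) * expm1(0.7 * 2),
               tolerance = 1e-12)
})

test_that("constraint violations and N(t) underflow yield -Inf, not errors", {
  ct <- coalescent_times(toy4())
  bad <- diversification_model("M4a", lambda0 = 1, alpha = -2, mu0 = 0.9,
                               N0 = 100)
  expect_identical(log_likelihood(bad, ct), -Inf)
  # enormous growth drives N(t_root) to underflow
  deep <- as_coalescent_times(c(600, 400, 200))
  m5 <- diversification_model("M5", lambda0 = 3, N0 = 100)
  expect_identical(log_likelihood(m5, deep), -Inf)
  expect_error(log_likelihood_hey(-1, 10, ct), "tau0")
})

test_that("time rescaling shifts the log-likelihood by (n-2) log c", {
  set.seed(47)
  ct <- coalescent_times(random_ultrametric(15))
  cc <- 2.7
  scaled <- as_coalescent_times(ct$node_depths * cc)
  cases <- list(
    list(diversification_model("M2", tau0 = 2, gamma = 0.3, N0 = 50),
         diversification_model("M2", tau0 = 2 / cc, gamma = 0.3 / cc,
                               N0 = 50)),
    list(diversification_model("M4a", lambda0 = 1, alpha = 0.4, mu0 = 0.3,
                               N0 = 50),
         diversification_model("M4a", lambda0 = 1 / cc, alpha = 0.4 / cc,
                               mu0 = 0.3 / cc, N0 = 50))
  )
  for (p in cases)
    expect_equal(log_likelihood(p[[2]], scaled),
                 log_likelihood(p[[1]], ct) - (ct$n - 2) * log(cc),
                 tolerance = 1e-8)
})
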