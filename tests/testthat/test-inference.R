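# fake fit/comparison builders for unit-testing the selection arithmetic
fake_fit <- function(model, estimates, logL = 0, n_obs = 20) {
  k <- diversification_models()$k[diversification_models()$model == model]
  structure(list(model = model, estimates = estimates, logL = logL, k = k,
                 n_obs = n_obs, aicc = aicc(logL, k, n_obs)),
            class = "coal_fit")
}

test_that("AICc reproduces the small-sample correction arithmetic", {
  expect_equal(aicc(-10, 2, 20), 20 + 4 + 12 / 17)
  expect_equal(aicc(0, 1, 10), 2 + 4 / 8)
  # one extra unit of log-likelihood is worth exactly 2 AICc units
  expect_equal(aicc(-9, 2, 20), aicc(-10, 2, 20) - 2)
  expect_error(aicc(0, 3, 4), "n_obs")
})

test_that("Akaike weights normalize and follow the logistic rule", {
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(51)
  x <- runif(9, 100, 200)
  expect_equal(sum(akaike_weights(x)), 1)
  # infinite AICc means zero weight; all-infinite is an error
  expect_equal(akaike_weights(c(10, Inf))[2], 0)
  expect_error(akaike_weights(c(Inf, Inf)), "infinite")
})

test_that("the optimizer matches the closed-form constant-turnover MLE", {
  set.seed(52)
  for (i in 1:5) {
    ct <- coalescent_times(random_ultrametric(sample(10:60, 1)))
    N0 <- ct$n + 20
    fit <- fit_model("M1", ct, N0 = N0, seed = i)
    j <- seq.int(2L, ct$n - 1L)
    analytic <- (ct$n - 2) * N0 / (2 * sum(j * (j - 1) / 2 * ct$internode))
    expect_equal(unname(fit$estimates[["tau0"]]), analytic,
                 tolerance = 1e-6)
    expect_equal(fit$logL, log_likelihood_hey(analytic, N0, ct),
                 tolerance = 1e-9)
  }
})

test_that("multi-start fits are reproducible given a seed", {
  set.seed(53)
  ct <- coalescent_times(random_ultrametric(25))
  f1 <- fit_model("M4c", ct, N0 = 50, seed = 99, restarts = 4)
  f2 <- fit_model("M4c", ct, N0 = 50, seed = 99, restarts = 4)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$logL, f2$logL)
})

test_that("insufficient data for a model's parameter count is an error", {
  ct <- coalescent_times(random_ultrametric(6))   # n_obs = 4
  expect_error(fit_model("M4d", ct, N0 = 10), "insufficient data")
  expect_error(fit_model("M1", ct, N0 = 3), "N0")
})

test_that("larger models never score below their nested submodels", {
  set.seed(54)
  st <- simulate_saturated(N0 = 40, tau0 = 1, seed = 7)
  cmp <- suppressMessages(compare_models(coalescent_times(st$tree),
                                         N0 = 40, seed = 8, restarts = 5))
  L <- function(m) cmp$fits[[m]]$logL
  expect_gte(L("M2"), L("M1") - 1e-6)
  expect_gte(L("M6"), L("M5") - 1e-6)
  expect_gte(L("M4a"), L("M3") - 1e-4)
  expect_gte(L("M4b"), L("M3") - 1e-4)
  expect_gte(L("M4d"), L("M4a") - 1e-4)
  expect_gte(L("M4d"), L("M4b") - 1e-4)
  # weights sum to one and the table is AICc-sorted
  expect_equal(sum(cmp$table$weight), 1)
  expect_true(!is.unsorted(cmp$table$AICc))
})

test_that("hypothesis probabilities implement best-in-subset selection", {
  # hand-built comparison: M1 and M5 tie as subset winners
  tab <- data.frame(
    model = c("M1", "M2", "M5"), k = c(1, 2, 1),
    logL = c(0, 0, 0), AICc = c(10, 14, 10))
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  cmp <- structure(list(table = tab, models = tab$model),
                   class = "coal_comparison")
  p <- hypothesis_probability(cmp, "diversity")
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(sum(p), 1)
  expect_equal(names(p), c("expanding", "saturated"))
  # the better subset winner takes the larger share
  tab2 <- tab; tab2$AICc <- c(10, 14, 12)
  tab2$weight <- akaike_weights(tab2$AICc)
  cmp2 <- structure(list(table = tab2, models = tab2$model),
                    class = "coal_comparison")
  p2 <- hypothesis_probability(cmp2, "diversity")
  expect_lt(p2[["expanding"]], 0.5)
  expect_equal(sum(p2), 1)
  expect_error(hypothesis_probability(cmp2, "nonsense"))
})

test_that("extinction fraction at present follows the model conventions", {
  expect_equal(extinction_fraction_at_present(
    fake_fit("M2", c(tau0 = 1, gamma = 0.2))), 1)
  expect_equal(extinction_fraction_at_present(
    fake_fit("M6", c(lambda0 = 1, alpha = 0.2))), 0)
  expect_equal(extinction_fraction_at_present(
    fake_fit("M3", c(lambda0 = 1, mu0 = 0.5))), 0.5)
  expect_equal(extinction_fraction_at_present(
    fake_fit("M4c", c(lambda0 = 1, alpha = 0, epsilon = 0.25))), 0.25)
})

test_that("AICc ranking is invariant under time rescaling of the tree", {
  set.seed(55)
  st <- simulate_saturated(N0 = 30, tau0 = 1, seed = 10)
  ct <- coalescent_times(st$tree)
  cc <- 5
  ct_scaled <- as_coalescent_times(ct$node_depths * cc)
  models <- c("M1", "M2", "M3", "M5", "M6")
  c1 <- suppressMessages(compare_models(ct, N0 = 30, models = models,
                                        seed = 1, restarts = 5))
  c2 <- suppressMessages(compare_models(ct_scaled, N0 = 30, models = models,
                                        seed = 1, restarts = 5))
  o1 <- c1$table$model
  o2 <- c2$table$model
  expect_equal(o1, o2)
  # and the AICc gaps shift by a common constant, so deltas agree
  expect_equal(c1$table$delta[match(models, c1$table$model)],
               c2$table$delta[match(models, c2$table$model)],
               tolerance = 1e-3)
})
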