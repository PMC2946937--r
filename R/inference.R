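# Maximum-likelihood fitting, AICc model selection, Akaike weights,
# hypothesis probabilities and extinction-fraction estimation.

.PENALTY <- -1e10

# fast internal constructor (no validation) for optimizer hot path
.spec <- function(model, params, N0) {
  structure(list(model = model, params = params, N0 = N0),
            class = "model_spec")
}

# optimizer-space parameterization: positive rates on log scale, variation
# coefficients untransformed, extinction fraction on logit scale.  M3 is
# fitted as (lambda0, epsilon = mu0/lambda0) so that the speciation >=
# extinction constraint holds by construction.
.THETA_NAMES <- list(
  M1  = "log_tau0",
  M2  = c("log_tau0", "gamma"),
  M3  = c("log_lambda0", "logit_epsilon"),
  M4a = c("log_lambda0", "alpha", "log_mu0"),
  M4b = c("log_lambda0", "log_mu0", "beta"),
  M4c = c("log_lambda0", "alpha", "logit_epsilon"),
  M4d = c("log_lambda0", "alpha", "log_mu0", "beta"),
  M5  = "log_lambda0",
  M6  = c("log_lambda0", "alpha")
)

# natural parameters -> optimizer space (inverse of .theta_to_params);
# used to warm-start a model from a fitted nested submodel
.params_to_theta <- function(model, p) {
  p <- as.list(p)
  clamp_eps <- function(e) min(max(e, 1e-6), 1 - 1e-6)
  switch(model,
    M1  = log(p$tau0),
    M2  = c(log(p$tau0), p$gamma),
    M3  = c(log(p$lambda0),
            stats::qlogis(clamp_eps(p$mu0 / p$lambda0))),
    M4a = c(log(p$lambda0), p$alpha, log(max(p$mu0, 1e-8 * p$lambda0))),
    M4b = c(log(p$lambda0), log(max(p$mu0, 1e-8 * p$lambda0)), p$beta),
    M4c = c(log(p$lambda0), p$alpha, stats::qlogis(clamp_eps(p$epsilon))),
    M4d = c(log(p$lambda0), p$alpha, log(max(p$mu0, 1e-8 * p$lambda0)),
            p$beta),
    M5  = log(p$lambda0),
    M6  = c(log(p$lambda0), p$alpha)
  )
}

.theta_to_params <- function(model, theta) {
  switch(model,
    M1  = c(tau0 = exp(theta[1])),
    M2  = c(tau0 = exp(theta[1]), gamma = theta[2]),
    M3  = {
      lam <- exp(theta[1])
      c(lambda0 = lam, mu0 = lam * stats::plogis(theta[2]))
    },
    M4a = c(lambda0 = exp(theta[1]), alpha = theta[2], mu0 = exp(theta[3])),
    M4b = c(lambda0 = exp(theta[1]), mu0 = exp(theta[2]), beta = theta[3]),
    M4c = c(lambda0 = exp(theta[1]), alpha = theta[2],
            epsilon = stats::plogis(theta[3])),
    M4d = c(lambda0 = exp(theta[1]), alpha = theta[2], mu0 = exp(theta[3]),
            beta = theta[4]),
    M5  = c(lambda0 = exp(theta[1])),
    M6  = c(lambda0 = exp(theta[1]), alpha = theta[2])
  )
}

# heuristic central starts.  For the saturated models the closed-form M1
# turnover MLE sets the rate scale.  For the expanding models the natural
# scale is the net diversification rate that carries the clade from a
# couple of species at the root to N0 at present, r0 = log(N0/2)/t_1;
# larger net rates make N(t) underflow on deep trees and would strand the
# simplex on the constraint-violation plateau.  Variation coefficients
# start at 0 and the extinction fraction at 1/2.
.theta_init <- function(model, times, N0, kappa) {
  lt <- log(.hey_mle_tau0(times, N0, kappa))
  lr <- log(max(log(N0 / 2), 1e-3) / times$depth)   # log net rate scale
  switch(model,
    M1  = lt,
    M2  = c(lt, 0),
    M3  = c(lr + log(2), 0),              # lambda0 = 2 r0, epsilon = 1/2
    M4a = c(lr + log(2), 0, lr),
    M4b = c(lr + log(2), lr, 0),
    M4c = c(lr + log(2), 0, 0),
    M4d = c(lr + log(2), 0, lr, 0),
    M5  = lr,
    M6  = c(lr, 0)
  )
}

# random restart around the heuristic start: rates log-uniform within a
# factor 30, coefficients uniform on +/- 3 e-foldings across the tree depth
.theta_random <- function(model, init, depth) {
  nm <- .THETA_NAMES[[model]]
  th <- init
  for (i in seq_along(nm)) {
    th[i] <- switch(substr(nm[i], 1, 5),
      log_t = ,
      log_l = ,
      log_m = init[i] + stats::runif(1, -log(30), log(30)),
      gamma = ,
      alpha = ,
      beta  = stats::runif(1, -3, 3) / depth,
      logit = stats::qlogis(stats::runif(1, 0.05, 0.95))
    )
  }
  th
}

#' Second-order Akaike Information Criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n_obs - k - 1)`, the small-sample
#' corrected AIC.  For internode-distance likelihoods `n_obs` is the
#' number of internode distances, i.e. tips - 2.
#'
#' @param logL Maximized log-likelihood (nats).
#' @param k Number of free parameters.
#' @param n_obs Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-10, k = 2, n_obs = 20)   # 24.70588...
#' @export
aicc <- function(logL, k, n_obs) {
  if (n_obs <= k + 1)
    stop("AICc undefined: n_obs must exceed k + 1 (got n_obs = ", n_obs,
         ", k = ", k, ")")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Akaike weights
#'
#' Normalized relative likelihoods `w_l = exp(-Delta_l/2) / sum_m
#' exp(-Delta_m/2)` with `Delta_l = AICc_l - min(AICc)`; the subtraction
#' of the minimum is also the numerically stable shift.  Infinite AICc
#' values (models excluded from the comparison) receive weight 0.
#'
#' @param aicc_values Numeric vector of AICc scores (at least two finite).
#' @return Weights summing to 1, same names/length as the input.
#' @examples
#' akaike_weights(c(10, 12))   # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  fin <- is.finite(aicc_values)
  if (!any(fin)) stop("all AICc values are infinite")
  delta <- aicc_values - min(aicc_values[fin])
  w <- ifelse(fin, exp(-delta / 2), 0)
  w / sum(w)
}

#' Fit one diversification model to a phylogeny by maximum likelihood
#'
#' Maximizes the coalescent internode-distance likelihood for one of the
#' nine models, using multi-start Nelder-Mead on transformed parameters
#' (rates on the log scale, variation coefficients untransformed, the
#' extinction fraction on the logit scale).  One start is a
#' method-of-moments-style heuristic (the closed-form constant-turnover
#' MLE sets the rate scale); the remaining starts are randomized.
#' Single-parameter models are optimized with Brent's method on a wide
#' bracket instead.  Parameter sets violating the speciation >= extinction
#' constraint are penalized rather than raised, so the simplex can
#' recover.
#'
#' @param model Model identifier (see [diversification_models()]).
#' @param times A [coalescent_times()] object or an ultrametric binary
#'   `phylo`.
#' @param N0 Present-day clade richness (assumed known; the likelihood
#'   only involves rate/N0 ratios, so it cannot be estimated).
#' @param kappa Coalescence-rate convention constant (see
#'   [log_likelihood()]).
#' @param restarts Number of optimizer starts (first is the heuristic).
#' @param seed Optional integer seed for reproducible restarts.
#' @param extra_starts Optional list of named natural-parameter vectors
#'   used as additional starts, e.g. the optimum of a nested submodel
#'   ([compare_models()] wires these automatically, which guarantees that
#'   a larger model never scores below a nested smaller one).
#' @return An object of class `"coal_fit"`: model id, parameter estimates
#'   on the natural scale, maximized log-likelihood, `k`, `n_obs`, AICc
#'   and convergence diagnostics.
#' @examples
#' tr <- ape::read.tree(text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
#' fit_model("M1", tr, N0 = 20)
#' @export
fit_model <- function(model, times, N0, kappa = 2, restarts = 10,
                      seed = NULL, extra_starts = list()) {
  model <- match.arg(model, .MODEL_IDS)
  if (inherits(times, "phylo")) times <- coalescent_times(times)
  stopifnot(inherits(times, "coalescent_times"))
  if (N0 < times$n) stop("N0 must be at least the number of tips")
  k <- length(.MODEL_PARAMS[[model]])
  n_obs <- times$n - 2L
  if (n_obs <= k + 1)
    stop("insufficient data for model ", model, ": need more than ",
         k + 3, " tips, got ", times$n)
  if (!is.null(seed)) set.seed(seed)

  init <- .theta_init(model, times, N0, kappa)
  # inadmissible points get a large penalty with a slope back towards the
  # heuristic start, so the simplex can escape the -Inf plateau
  penalize <- function(theta) .PENALTY - sum(pmin((theta - init)^2, 1e4))
  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50))
      return(penalize(theta))
    params <- .theta_to_params(model, theta)
    if (any(!is.finite(params))) return(penalize(theta))
    ll <- log_likelihood(.spec(model, params, N0), times, kappa = kappa)
    if (!is.finite(ll)) return(penalize(theta))
    ll
  }
  starts <- c(list(init),
              lapply(extra_starts, function(p) .params_to_theta(model, p)),
              lapply(seq_len(max(restarts - 1, 0)), function(i)
                .theta_random(model, init, times$depth)))
  vals <- rep(NA_real_, length(starts))
  best <- NULL
  for (r in seq_along(starts)) {
    th0 <- starts[[r]]
    res <- if (k == 1) {
      o <- stats::optimize(function(x) obj(x), lower = th0 - 12,
                           upper = th0 + 12, maximum = TRUE, tol = 1e-10)
      list(par = o$maximum, value = o$objective)
    } else {
      o <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = 1e-10,
                                       maxit = 2000))
      list(par = o$par, value = o$value)
    }
    vals[r] <- res$value
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (!is.finite(best$value) || best$value <= .PENALTY / 10)
    stop("all restarts diverged for model ", model,
         " (best objective ", format(best$value), ")")
  if (k > 1) {   # polish the winner
    o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(fnscale = -1, reltol = 1e-12,
                                     maxit = 2000))
    if (o$value > best$value) best <- list(par = o$par, value = o$value)
  }
  params <- .theta_to_params(model, best$par)
  structure(list(
    model = model,
    estimates = params,
    logL = best$value,
    k = k,
    n_obs = n_obs,
    n = times$n,
    N0 = N0,
    kappa = kappa,
    aicc = aicc(best$value, k, n_obs),
    depth = times$depth,
    convergence = list(restarts = restarts, values = vals,
                       spread = max(vals[is.finite(vals)]) -
                                stats::median(vals[is.finite(vals)]))
  ), class = "coal_fit")
}

#' @export
print.coal_fit <- function(x, ...) {
  cat("Coalescent diversification fit:", x$model, "\n")
  cat("  ", .MODEL_DESC[[x$model]], "\n", sep = "")
  cat("  estimates: ",
      paste(sprintf("%s = %.5g", names(x$estimates), x$estimates),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  logL = %.4f  k = %d  n_obs = %d  AICc = %.4f\n",
              x$logL, x$k, x$n_obs, x$aicc))
  invisible(x)
}

#' @export
coef.coal_fit <- function(object, ...) object$estimates

#' @export
logLik.coal_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

# model_spec corresponding to a fit
.fit_spec <- function(fit) .spec(fit$model, fit$estimates, fit$N0)

#' Fit and compare the nine diversification models
#'
#' Fits each requested model to a phylogeny with [fit_model()], ranks them
#' by AICc, computes Akaike weights over the full candidate set, evaluates
#' the three hypothesis partitions (expanding vs saturated diversity,
#' time-varying vs constant rates, extinction present vs absent) via the
#' best-in-subset rule, and reports the extinction fraction at present of
#' the overall best model.  Models that cannot be fitted (too few tips for
#' their parameter count, or all starts diverging) are retained with
#' `AICc = +Inf` and weight 0, with a notice.
#'
#' Exact AICc ties are broken in favour of fewer parameters, then by the
#' fixed model order M1, M2, M3, M4a, M4b, M4c, M4d, M5, M6.
#'
#' @inheritParams fit_model
#' @param models Character vector of model ids to fit (default: all nine).
#' @return An object of class `"coal_comparison"`: per-model fits, a
#'   ranked comparison table, the best model id, the three hypothesis
#'   probability pairs and the extinction fraction at present.
#' @seealso [hypothesis_probability()], [extinction_fraction_at_present()]
#' @export
compare_models <- function(times, N0, models = .MODEL_IDS, kappa = 2,
                           restarts = 10, seed = NULL) {
  if (inherits(times, "phylo")) times <- coalescent_times(times)
  models <- match.arg(models, .MODEL_IDS, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", length(models)); names(fits) <- models
  est <- function(m) if (!is.null(fits[[m]])) as.list(fits[[m]]$estimates)
  # warm starts from fitted nested (or limiting) submodels: a larger
  # model is then never scored below a submodel it contains
  warm <- function(m) {
    s <- list()
    add <- function(p) if (!is.null(p) && all(is.finite(unlist(p))))
      s[[length(s) + 1]] <<- p
    e1 <- est("M1"); e2 <- est("M2"); e3 <- est("M3"); e5 <- est("M5")
    e6 <- est("M6"); e4a <- est("M4a"); e4b <- est("M4b"); e4c <- est("M4c")
    switch(m,
      M2 = add(c(e1, gamma = 0)),
      M3 = {
        if (!is.null(e1)) add(list(lambda0 = e1$tau0,
                                   mu0 = e1$tau0 * (1 - 1e-6)))
        if (!is.null(e5)) add(list(lambda0 = e5$lambda0, mu0 = 0))
      },
      M6 = add(c(e5, alpha = 0)),
      M4a = {
        if (!is.null(e3)) add(c(e3[c("lambda0", "mu0")], alpha = 0))
        if (!is.null(e6)) add(list(lambda0 = e6$lambda0, alpha = e6$alpha,
                                   mu0 = 0))
      },
      M4b = {
        if (!is.null(e3)) add(c(e3[c("lambda0", "mu0")], beta = 0))
        if (!is.null(e5)) add(list(lambda0 = e5$lambda0, mu0 = 0, beta = 0))
      },
      M4c = {
        if (!is.null(e6)) add(list(lambda0 = e6$lambda0, alpha = e6$alpha,
                                   epsilon = 0))
        if (!is.null(e3)) add(list(lambda0 = e3$lambda0, alpha = 0,
                                   epsilon = e3$mu0 / e3$lambda0))
        if (!is.null(e2)) add(list(lambda0 = e2$tau0, alpha = e2$gamma,
                                   epsilon = 1))
      },
      M4d = {
        if (!is.null(e4a)) add(c(e4a, beta = 0))
        if (!is.null(e4b)) add(list(lambda0 = e4b$lambda0, alpha = 0,
                                    mu0 = e4b$mu0, beta = e4b$beta))
        if (!is.null(e4c)) add(list(lambda0 = e4c$lambda0,
                                    alpha = e4c$alpha,
                                    mu0 = e4c$epsilon * e4c$lambda0,
                                    beta = e4c$alpha))
      },
      NULL)
    s
  }
  fit_order <- intersect(c("M1", "M2", "M5", "M3", "M6", "M4a", "M4b",
                           "M4c", "M4d"), models)
  for (m in fit_order) {
    fits[m] <- list(tryCatch(fit_model(m, times, N0, kappa = kappa,
                                       restarts = restarts,
                                       extra_starts = warm(m)),
      error = function(e) {
        message("model ", m, " excluded from comparison: ",
                conditionMessage(e))
        NULL
      }))
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no model could be fitted")
  aiccs <- vapply(fits, function(f) if (is.null(f)) Inf else f$aicc,
                  numeric(1))
  ks <- vapply(models, function(m) length(.MODEL_PARAMS[[m]]), integer(1))
  w <- akaike_weights(aiccs)
  # lowest AICc; ties -> fewer parameters -> fixed model order
  best <- models[order(aiccs, ks, match(models, .MODEL_IDS))][1]
  tab <- data.frame(
    model = models, k = ks,
    logL = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logL,
                  numeric(1)),
    AICc = aiccs, delta = aiccs - min(aiccs), weight = w,
    row.names = NULL
  )
  tab <- tab[order(tab$AICc, tab$k), ]
  cmp <- structure(list(
    fits = fits, table = tab, best = best, models = models,
    N0 = N0, n = times$n, kappa = kappa
  ), class = "coal_comparison")
  cmp$hypotheses <- list(
    diversity  = hypothesis_probability(cmp, "diversity"),
    rates      = hypothesis_probability(cmp, "rates"),
    extinction = hypothesis_probability(cmp, "extinction")
  )
  cmp$extinction_fraction <-
    extinction_fraction_at_present(fits[[best]])
  cmp
}

.PARTITIONS <- list(
  diversity = list(
    A = c("M3", "M4a", "M4b", "M4c", "M4d", "M5", "M6"),   # expanding
    B = c("M1", "M2"),                                     # saturated
    labels = c("expanding", "saturated")),
  rates = list(
    A = c("M2", "M4a", "M4b", "M4c", "M4d", "M6"),         # time-varying
    B = c("M1", "M3", "M5"),                               # constant
    labels = c("varying", "constant")),
  extinction = list(
    A = c("M1", "M2", "M3", "M4a", "M4b", "M4c", "M4d"),   # extinction
    B = c("M5", "M6"),                                     # none
    labels = c("extinction", "no_extinction"))
)

#' Relative probability of two competing diversification hypotheses
#'
#' Implements the best-in-subset rule: within each side of a partition of
#' the nine models the lowest-AICc model is selected, and the relative
#' probability of the two selected models is computed from their Akaike
#' weights (taken over the full fitted candidate set) as
#' `w_A / (w_A + w_B)` and `w_B / (w_A + w_B)`.
#'
#' The partitions are `"diversity"` (expanding M3-M6 vs saturated M1-M2),
#' `"rates"` (time-varying M2, M4a-M4d, M6 vs constant M1, M3, M5) and
#' `"extinction"` (extinction present M1-M4d vs absent M5, M6).
#'
#' @param comparison A [compare_models()] result.
#' @param partition One of `"diversity"`, `"rates"`, `"extinction"`.
#' @return A named numeric vector of two probabilities summing to 1.
#' @export
hypothesis_probability <- function(comparison,
                                   partition = c("diversity", "rates",
                                                 "extinction")) {
  stopifnot(inherits(comparison, "coal_comparison"))
  partition <- match.arg(partition)
  part <- .PARTITIONS[[partition]]
  tab <- comparison$table
  pick <- function(side) {
    sub <- tab[tab$model %in% side, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty subset in partition '", partition, "'")
    sub[order(sub$AICc, sub$k), ][1, ]
  }
  a <- pick(part$A); b <- pick(part$B)
  tot <- a$weight + b$weight
  # tot > 0 always holds when all nine models are fitted (the global best
  # lies in one subset); the fallback covers partial candidate sets
  p <- if (tot > 0) c(a$weight, b$weight) / tot
       else if (a$AICc <= b$AICc) c(1, 0) else c(0, 1)
  names(p) <- part$labels
  p
}

#' Extinction fraction at present implied by a fitted model
#'
#' Maps a fitted model to the ratio of extinction to speciation rate at
#' the present: 1 for the saturated-diversity models (M1, M2), where
#' every speciation is tied to an extinction; 0 for the extinction-free
#' models (M5, M6); and `mu(0)/lambda(0)` from the fitted parameters
#' otherwise.
#'
#' @param fit A `"coal_fit"` object (conventionally the lowest-AICc
#'   model).
#' @return A number in `[0, 1]`.
#' @export
extinction_fraction_at_present <- function(fit) {
  stopifnot(inherits(fit, "coal_fit"))
  e <- fit$estimates
  switch(fit$model,
    M1 = , M2 = 1,
    M5 = , M6 = 0,
    M4c = unname(e[["epsilon"]]),
    unname(min(1, e[["mu0"]] / e[["lambda0"]]))
  )
}

#' @export
print.coal_comparison <- function(x, digits = 4, ...) {
  cat("Coalescent diversification model comparison (", x$n, " tips, N0 = ",
      x$N0, ")\n\n", sep = "")
  tab <- x$table
  tab$logL <- round(tab$logL, digits)
  tab$AICc <- round(tab$AICc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab, row.names = FALSE)
  cat("\nBest model:", x$best, "-", .MODEL_DESC[[x$best]], "\n")
  h <- x$hypotheses
  cat(sprintf("P(expanding diversity) = %.3f   P(time-varying rates) = %.3f   P(extinction) = %.3f\n",
              h$diversity[["expanding"]], h$rates[["varying"]],
              h$extinction[["extinction"]]))
  cat(sprintf("Extinction fraction at present (best model): %.3f\n",
              x$extinction_fraction))
  invisible(x)
}

#' @export
summary.coal_comparison <- function(object, ...) print(object, ...)

#' @export
plot.coal_comparison <- function(x, ...) {
  tab <- x$table[match(x$models, x$table$model), ]
  varying <- diversification_models()
  cols <- ifelse(varying$varying[match(tab$model, varying$model)],
                 "steelblue", "grey60")
  graphics::barplot(tab$weight, names.arg = tab$model, col = cols,
                    ylab = "Akaike weight", ylim = c(0, 1),
                    main = paste("Model probabilities (best:", x$best, ")"),
                    ...)
  invisible(x)
}

#' Simulate phylogenies from a fitted model
#'
#' Draws reconstructed phylogenies from the generating process of a
#' fitted model, e.g. for posterior-predictive checks.  Saturated models
#' use the Moran-type turnover simulator; expanding models use the
#' birth-death simulator run for the observed root depth.
#'
#' @param object A `"coal_fit"` object.
#' @param nsim Number of trees.
#' @param seed Optional integer seed.
#' @param duration Simulation length; defaults to the fitted tree's root
#'   depth for birth-death models and to the saturated simulator's
#'   default otherwise.
#' @param ... Unused.
#' @return A list of `"sim_tree"` objects.
#' @export
simulate.coal_fit <- function(object, nsim = 1, seed = NULL,
                              duration = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- .fit_spec(object)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    out[[i]] <- if (object$model %in% c("M1", "M2")) {
      simulate_saturated(N0 = object$N0,
                         tau0 = object$estimates[["tau0"]],
                         gamma = if (object$model == "M2")
                                   object$estimates[["gamma"]] else 0,
                         duration = duration)
    } else {
      simulate_birth_death(spec, duration = duration %||% object$depth)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
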