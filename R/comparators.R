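# Summary statistics and branch-length-distribution comparators: the
# gamma statistic, and maximum-likelihood fits of candidate distributions
# (exponential, Weibull, lognormal, normal) to internal branch lengths.

#' Gamma statistic of node depths
#'
#' Computes the Pybus-Harvey gamma statistic, a standardized summary of
#' where nodes sit in an ultrametric phylogeny.  With `g_k` the interval
#' during which exactly k lineages exist (k = 2..n, *including* the
#' terminal interval between the most recent node and the present, unlike
#' the coalescent likelihood), `T_i = sum_{k=2}^{i} k g_k` and `T = T_n`:
#'
#' `gamma = [ mean(T_2 ... T_{n-1}) - T/2 ] / [ T * sqrt(1/(12(n-2))) ]`
#'
#' Under the pure-birth Yule model gamma follows the standard normal
#' distribution; negative values indicate nodes crowded towards the root
#' (e.g. a slowdown in speciation).
#'
#' @param x A binary ultrametric `phylo`, a [coalescent_times()] object,
#'   or a `"sim_tree"`.
#' @return The gamma statistic (a scalar).
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
#' gamma_statistic(tr)
#' @export
gamma_statistic <- function(x) {
  if (inherits(x, "sim_tree")) x <- x$tree
  if (inherits(x, "phylo")) x <- coalescent_times(x)
  stopifnot(inherits(x, "coalescent_times"))
  n <- x$n
  g <- c(x$internode, x$terminal)          # g_2 ... g_n
  k <- seq.int(2L, n)
  Ti <- cumsum(k * g)                      # T_2 ... T_n
  T_tot <- Ti[n - 1]
  (mean(Ti[seq_len(n - 2)]) - T_tot / 2) /
    (T_tot * sqrt(1 / (12 * (n - 2))))
}

#' Internal branch lengths of a phylogeny
#'
#' Extracts the lengths of internal branches (between two internal
#' nodes).  Terminal branches are excluded because their lengths do not
#' reflect waiting times between speciation events; a root edge, if
#' present, is excluded as well.
#'
#' @param tree A `phylo` or `"sim_tree"` object.
#' @return An object of class `"branch_length_sample"`: a list with the
#'   numeric `lengths` and their `count`.
#' @export
branch_length_sample <- function(tree) {
  if (inherits(tree, "sim_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  lens <- tree$edge.length[internal]
  structure(list(lengths = lens, count = length(lens)),
            class = "branch_length_sample")
}

#' @export
print.branch_length_sample <- function(x, ...) {
  cat("Internal branch lengths: n =", x$count,
      " mean =", format(mean(x$lengths)), "\n")
  invisible(x)
}

.BL_FAMILIES <- c("exponential", "weibull", "lognormal", "normal")
.BL_K <- c(exponential = 1L, weibull = 2L, lognormal = 2L, normal = 2L)

.bl_loglik <- function(family, x, params) {
  switch(family,
    exponential = sum(stats::dexp(x, rate = params[["rate"]], log = TRUE)),
    weibull = sum(stats::dweibull(x, shape = params[["shape"]],
                                  scale = params[["scale"]], log = TRUE)),
    lognormal = sum(stats::dlnorm(x, meanlog = params[["meanlog"]],
                                  sdlog = params[["sdlog"]], log = TRUE)),
    normal = sum(stats::dnorm(x, mean = params[["mean"]],
                              sd = params[["sd"]], log = TRUE))
  )
}

#' Maximum-likelihood fit of a distribution to branch lengths
#'
#' Fits one of four candidate families to a sample of internal branch
#' lengths and scores it by AICc.  Only the Weibull corresponds to a
#' speciation rate varying with lineage age; the others are
#' constant-rate families.  Closed-form maximum-likelihood estimates are
#' used for the exponential, lognormal and normal families; the Weibull
#' (and, on request, any family) is maximized numerically.
#'
#' @param x A [branch_length_sample()] or a numeric vector of branch
#'   lengths.
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"normal"`.
#' @param method `"auto"` (closed form where available) or `"optim"`
#'   (numerical maximization for every family; Nelder-Mead for
#'   two-parameter families, Brent for one).
#' @return A list of class `"bl_fit"`: family, parameter estimates,
#'   log-likelihood, parameter count `k`, `n_obs` and AICc.
#' @examples
#' set.seed(1)
#' fit_branch_length_distribution(rexp(200, 2), "exponential")
#' @export
fit_branch_length_distribution <- function(x, family = .BL_FAMILIES,
                                           method = c("auto", "optim")) {
  if (inherits(x, "branch_length_sample")) x <- x$lengths
  family <- match.arg(family)
  method <- match.arg(method)
  x <- as.numeric(x)
  k <- .BL_K[[family]]
  n <- length(x)
  if (n <= k + 1)
    stop("need more than ", k + 1, " branch lengths for the ", family,
         " family")
  if (family %in% c("exponential", "weibull", "lognormal") && any(x <= 0))
    stop("nonpositive branch lengths are incompatible with the ", family,
         " family")
  closed <- switch(family,
    exponential = c(rate = 1 / mean(x)),
    lognormal = {
      lx <- log(x)
      c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    normal = c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2))),
    weibull = NULL
  )
  params <- if (method == "auto" && !is.null(closed)) closed else {
    init <- switch(family,
      exponential = log(1 / mean(x)),
      weibull = c(0, log(mean(x))),                  # log shape, log scale
      lognormal = c(mean(log(x)), log(stats::sd(log(x)))),
      normal = c(mean(x), log(stats::sd(x)))
    )
    to_params <- switch(family,
      exponential = function(th) c(rate = exp(th[1])),
      weibull = function(th) c(shape = exp(th[1]), scale = exp(th[2])),
      lognormal = function(th) c(meanlog = th[1], sdlog = exp(th[2])),
      normal = function(th) c(mean = th[1], sd = exp(th[2]))
    )
    obj <- function(th) {
      ll <- .bl_loglik(family, x, to_params(th))
      if (!is.finite(ll)) -1e10 else ll
    }
    if (length(init) == 1) {
      o <- stats::optimize(obj, lower = init - 12, upper = init + 12,
                           maximum = TRUE, tol = 1e-12)
      to_params(o$maximum)
    } else {
      o <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = 1e-12,
                                       maxit = 5000))
      to_params(o$par)
    }
  }
  logL <- .bl_loglik(family, x, params)
  structure(list(family = family, params = params, logL = logL, k = k,
                 n_obs = n, aicc = aicc(logL, k, n)),
            class = "bl_fit")
}

#' @export
print.bl_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s; logL = %.4f, AICc = %.4f (n = %d)\n",
              x$family,
              paste(sprintf("%s = %.5g", names(x$params), x$params),
                    collapse = ", "),
              x$logL, x$aicc, x$n_obs))
  invisible(x)
}

#' Branch-length-distribution model selection
#'
#' Benchmarks the branch-length-distribution approach to detecting rate
#' variation: extracts the internal branch lengths of a tree, fits the
#' exponential, Weibull, lognormal and normal families by maximum
#' likelihood, and selects the family with lowest AICc.  A Weibull win
#' suggests speciation rates that depend on lineage age; the other three
#' families correspond to age-constant speciation.  The procedure is
#' deterministic given the tree.
#'
#' @param tree A `phylo` or `"sim_tree"` object with at least 5 internal
#'   branches.
#' @return A list of class `"venditti_selection"`: per-family fits, an
#'   AICc table and the winning family.
#' @export
venditti_model_selection <- function(tree) {
  sample <- branch_length_sample(tree)
  if (sample$count < 5)
    stop("need at least 5 internal branches, got ", sample$count)
  fits <- lapply(.BL_FAMILIES, function(f)
    fit_branch_length_distribution(sample, f))
  names(fits) <- .BL_FAMILIES
  tab <- data.frame(
    family = .BL_FAMILIES,
    k = unname(.BL_K[.BL_FAMILIES]),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$AICc, tab$k), ]
  structure(list(fits = fits, table = tab, best = tab$family[1],
                 n_branches = sample$count),
            class = "venditti_selection")
}

#' @export
print.venditti_selection <- function(x, ...) {
  cat("Branch-length distribution comparison (", x$n_branches,
      " internal branches)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("Best family:", x$best, "\n")
  invisible(x)
}

#' Posterior-predictive check of a fitted model via the gamma statistic
#'
#' Simulates phylogenies from a fitted diversification model, subsamples
#' them at the empirical sampling fraction, and locates the observed
#' gamma statistic within the simulated gamma distribution.  A quantile
#' far into either tail indicates that the best-fit model does not
#' reproduce the observed branch-length pattern.
#'
#' @param fit A `"coal_fit"` object (typically the best model of a
#'   [compare_models()] run).
#' @param times The observed tree (`phylo` or [coalescent_times()]).
#' @param nsim Number of simulated phylogenies.
#' @param f Sampling fraction applied to each simulated tree.
#' @param seed Optional integer seed.
#' @return A list with `observed` (gamma of the data), `simulated`
#'   (vector of simulated gammas) and `quantile` (the proportion of
#'   simulated gammas below the observed one).
#' @export
posterior_predictive_gamma <- function(fit, times, nsim = 100, f = 1,
                                       seed = NULL) {
  stopifnot(inherits(fit, "coal_fit"))
  obs <- gamma_statistic(times)
  sims <- simulate(fit, nsim = nsim, seed = seed)
  gammas <- vapply(sims, function(st) {
    tr <- if (f < 1) sample_tips(st, f) else st$tree
    gamma_statistic(tr)
  }, numeric(1))
  list(observed = obs, simulated = gammas,
       quantile = mean(gammas <= obs))
}
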