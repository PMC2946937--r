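# Coalescent likelihood of internode distances.
#
# Backwards in time, while j sampled lineages coexist they coalesce at
# rate rho_j(t) = kappa * [j(j-1)/2] * lambda(t) / N(t): the Kingman pair
# rate 1/N per generation, with the generation time (time for a complete
# turnover of species) equal to 1/lambda(t), scaled by the number of
# pairs and by a convention constant kappa.  The package default kappa = 2
# is calibrated against the Moran-type turnover simulator, whose pair-
# coalescence rate is 2*tau/N per unit time (see the methods vignette);
# kappa rescales absolute rate estimates but cancels from all model
# comparisons.
#
# The log-likelihood of the n - 2 internode distances, conditioning on n
# and on the depth of the most recent node, is
#   sum_{j=2}^{n-1} [ log rho_j(t_{j-1}) - Lambda_j(t_j, t_{j-1}) ]
# with Lambda_j(a, b) = int_a^b rho_j(s) ds.

.KAPPA_DEFAULT <- 2

# exp(xa) * (exp(xb - xa) - 1), a cancellation-safe e^xb - e^xa
.dexp <- function(xa, xb) exp(xa) * expm1(xb - xa)

# ---- Gauss-Legendre panels (cached) ---------------------------------------

# nodes/weights on [0, 1]; Golub-Welsch via the symmetric Jacobi matrix
.gl_rule <- function(order) {
  key <- as.character(order)
  rule <- .coaldiv_cache[[paste0("gl", key)]]
  if (!is.null(rule)) return(rule)
  i <- seq_len(order - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, order, order)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  o <- order(x)
  rule <- list(x = (x[o] + 1) / 2, w = w[o] / 2)
  .coaldiv_cache[[paste0("gl", key)]] <- rule
  rule
}

# ---- int_a^b lambda(s)/N(s) ds --------------------------------------------

# log of the integrand lambda(s) / N(s), vectorized over s
.log_lambda_over_N <- function(spec, s) {
  lam <- rates_at(spec, s)$speciation
  log(lam) + .net_integral(spec, s) - log(spec$N0)
}

# fixed-order Gauss-Legendre estimate for paired interval vectors
.gl_panel <- function(spec, a, b, order) {
  rule <- .gl_rule(order)
  len <- b - a
  s <- outer(a, rule$x * 0, "+") + outer(len, rule$x)   # m x order nodes
  f <- exp(.log_lambda_over_N(spec, as.vector(s)))
  dim(f) <- dim(s)
  len * as.vector(f %*% rule$w)
}

# vectorized quadrature with a scalar adaptive fallback for the few
# intervals where two Gauss-Legendre orders disagree.  check = FALSE
# skips the refinement (used in the optimizer hot loop, where intervals
# are short internode distances and a single panel is ample).
.quad_lambda_over_N <- function(spec, a, b, rel_tol = 1e-10, check = TRUE) {
  out <- numeric(length(a))
  pos <- b > a
  if (!any(pos)) return(out)
  a1 <- a[pos]; b1 <- b[pos]
  if (!check) {
    out[pos] <- .gl_panel(spec, a1, b1, 25L)
    return(out)
  }
  i1 <- .gl_panel(spec, a1, b1, 21L)
  i2 <- .gl_panel(spec, a1, b1, 43L)
  scale <- pmax(abs(i2), 1e-12)
  bad <- !is.finite(i2) | abs(i2 - i1) > rel_tol * scale
  if (any(bad)) {
    f <- function(s) exp(.log_lambda_over_N(spec, s))
    for (k in which(bad)) {
      i2[k] <- tryCatch(
        stats::integrate(f, a1[k], b1[k], rel.tol = 1e-12,
                         subdivisions = 400L)$value,
        error = function(e) NA_real_)
      if (!is.finite(i2[k])) i2[k] <- Inf
    }
  }
  out[pos] <- i2
  out
}

# closed forms where int lambda/N is elementary; quadrature otherwise.
# a, b are paired vectors with 0 <= a <= b.
.lambda_over_N_integral <- function(spec, a, b, fast = FALSE) {
  p <- as.list(spec$params)
  N0 <- spec$N0
  switch(spec$model,
    M1 = p$tau0 * (b - a) / N0,
    M2 = if (abs(p$gamma) < .COEF_EPS) p$tau0 * (b - a) / N0
         else (p$tau0 / (p$gamma * N0)) * .dexp(p$gamma * a, p$gamma * b),
    M3 = {
      r <- p$lambda0 - p$mu0
      if (abs(r) < .COEF_EPS) p$lambda0 * (b - a) / N0
      else (p$lambda0 / (r * N0)) * .dexp(r * a, r * b)
    },
    M5 = if (p$lambda0 < .COEF_EPS) p$lambda0 * (b - a) / N0
         else .dexp(p$lambda0 * a, p$lambda0 * b) / N0,
    M6 = {
      if (abs(p$alpha) < .COEF_EPS) {
        if (p$lambda0 < .COEF_EPS) p$lambda0 * (b - a) / N0
        else .dexp(p$lambda0 * a, p$lambda0 * b) / N0
      } else {
        X <- function(t) (p$lambda0 / p$alpha) * expm1(p$alpha * t)
        .dexp(X(a), X(b)) / N0
      }
    },
    M4c = {
      cc <- 1 - p$epsilon
      if (cc < .COEF_EPS) {            # epsilon ~ 1: N(t) = N0
        if (abs(p$alpha) < .COEF_EPS) p$lambda0 * (b - a) / N0
        else (p$lambda0 / (p$alpha * N0)) * .dexp(p$alpha * a, p$alpha * b)
      } else if (abs(p$alpha) < .COEF_EPS) {
        r <- cc * p$lambda0
        if (r < .COEF_EPS) p$lambda0 * (b - a) / N0
        else (p$lambda0 / (r * N0)) * .dexp(r * a, r * b)
      } else {
        X <- function(t) cc * (p$lambda0 / p$alpha) * expm1(p$alpha * t)
        .dexp(X(a), X(b)) / (cc * N0)
      }
    },
    M4a = ,
    M4b = ,
    M4d = .quad_lambda_over_N(spec, a, b, check = !fast)
  )
}

# ---- exported operations ---------------------------------------------------

#' Cumulative coalescence rate over a time interval
#'
#' Computes `Lambda_j(a, b) = int_a^b rho_j(s) ds`, the integrated
#' coalescence rate for `j` concurrent lineages between times `a` and `b`
#' before present, where `rho_j(t) = kappa * j(j-1)/2 * lambda(t)/N(t)`.
#' Closed forms are used for models M1, M2, M3, M4c, M5 and M6 (the
#' integrand is elementary there); adaptive Gauss-Legendre quadrature is
#' used for M4a, M4b and M4d.
#'
#' @param spec A [diversification_model()] object.
#' @param j Number of concurrent lineages (integer >= 2).
#' @param a,b Interval endpoints, `0 <= a <= b` (time before present).
#' @param kappa Coalescence-rate convention constant; the package default
#'   2 matches the Moran-type turnover simulator (see the vignette).
#' @return The nonnegative integrated rate `Lambda_j(a, b)`.
#' @examples
#' m <- diversification_model("M1", tau0 = 1, N0 = 100)
#' cumulative_rate(m, j = 2, a = 0, b = 5)   # 2 * 1 * (5/100)
#' @export
cumulative_rate <- function(spec, j, a, b, kappa = 2) {
  stopifnot(inherits(spec, "model_spec"))
  if (j < 2) stop("j must be >= 2")
  if (a < 0 || b < a) stop("need 0 <= a <= b")
  val <- kappa * j * (j - 1) / 2 * .lambda_over_N_integral(spec, a, b)
  if (!is.finite(val))
    stop(sprintf("integrand overflow in Lambda_%d over [%g, %g]", j, a, b))
  val
}

#' Log-likelihood of internode distances under a diversification model
#'
#' Evaluates the coalescent log-likelihood of the n - 2 internode
#' distances of a sampled ultrametric phylogeny under any of the nine
#' diversification scenarios, conditioning on the number of tips and on
#' the depth of the most recent node (the terminal interval contributes
#' no factor).  Parameter sets violating the requirement that the
#' speciation rate never falls below the extinction rate on `[0, t_1]`,
#' or driving the expected diversity `N(t)` to numerical underflow,
#' return `-Inf` rather than raising, so that optimizers can traverse
#' them.
#'
#' @param spec A [diversification_model()] object; its `N0` must be at
#'   least the number of sampled tips.
#' @param times A [coalescent_times()] object (or an ultrametric binary
#'   `phylo`, which is converted).
#' @inheritParams cumulative_rate
#' @return Log-likelihood in nats (possibly `-Inf`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' m <- diversification_model("M1", tau0 = 50, N0 = 100)  # rho_2 = 1
#' log_likelihood(m, coalescent_times(tr))                # log(1) - 1
#' @export
log_likelihood <- function(spec, times, kappa = 2) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(times, "phylo")) times <- coalescent_times(times)
  stopifnot(inherits(times, "coalescent_times"))
  if (spec$N0 < times$n)
    stop("N0 (", spec$N0, ") must be at least the number of tips (",
         times$n, ")")
  if (!validate_constraint(spec, times$depth)) return(-Inf)
  d <- times$node_depths                    # t_1 > ... > t_{n-1}
  m <- length(d) - 1L                       # n - 2 intervals
  a <- d[-1]; b <- d[-length(d)]            # interval j: (t_j, t_{j-1})
  j <- seq.int(2L, m + 1L)
  pairs <- j * (j - 1) / 2
  lamN <- .lambda_over_N_integral(spec, a, b, fast = TRUE)
  log_rho <- log(kappa * pairs) + .log_lambda_over_N(spec, b)
  terms <- log_rho - kappa * pairs * lamN
  if (any(!is.finite(terms))) {
    if (isTRUE(getOption("coaldiv.verbose", FALSE)))
      message("log_likelihood: non-finite density (N(t) underflow or rate ",
              "overflow); returning -Inf")
    return(-Inf)
  }
  sum(terms)
}

#' Closed-form Hey-model log-likelihood
#'
#' Under the saturated-diversity, constant-turnover model (M1) each
#' internode distance g_j is exponential with constant rate
#' `kappa * j(j-1)/2 * tau0 / N0`, and the log-likelihood has a closed
#' form.  It depends on `tau0` and `N0` only through their ratio, which
#' is why the present-day clade size must be supplied rather than
#' estimated.  Serves as an independent oracle for the generic
#' [log_likelihood()] path.
#'
#' @param tau0 Turnover rate (> 0).
#' @param N0 Present-day clade richness (> 0).
#' @param times A [coalescent_times()] object (or ultrametric binary
#'   `phylo`).
#' @inheritParams cumulative_rate
#' @return Log-likelihood in nats.
#' @export
log_likelihood_hey <- function(tau0, N0, times, kappa = 2) {
  if (!is.numeric(tau0) || tau0 <= 0) stop("tau0 must be > 0")
  if (!is.numeric(N0) || N0 <= 0) stop("N0 must be > 0")
  if (inherits(times, "phylo")) times <- coalescent_times(times)
  stopifnot(inherits(times, "coalescent_times"))
  j <- seq.int(2L, times$n - 1L)
  r <- kappa * j * (j - 1) / 2 * tau0 / N0
  sum(log(r) - r * times$internode)
}

# closed-form M1 maximum-likelihood estimate of tau0 given N0:
# tau0_hat = (n-2) * N0 / (kappa * sum_j C(j,2) g_j)
.hey_mle_tau0 <- function(times, N0, kappa = 2) {
  j <- seq.int(2L, times$n - 1L)
  (times$n - 2) * N0 / (kappa * sum(j * (j - 1) / 2 * times$internode))
}
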