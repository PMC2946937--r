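# Nine diversification scenarios: rate functions and expected diversity.
#
# Time convention: t is measured backwards from the present (t = 0 at the
# tips, t > 0 in the past).  All "rate at present" parameters (tau0,
# lambda0, mu0) are anchored at t = 0, and exponential variation
# coefficients act on time-before-present, e.g. lambda(t) = lambda0 *
# exp(alpha * t).  A positive coefficient therefore means the rate was
# higher in the past and has decayed towards the present.

.MODEL_IDS <- c("M1", "M2", "M3", "M4a", "M4b", "M4c", "M4d", "M5", "M6")

.MODEL_PARAMS <- list(
  M1  = "tau0",
  M2  = c("tau0", "gamma"),
  M3  = c("lambda0", "mu0"),
  M4a = c("lambda0", "alpha", "mu0"),
  M4b = c("lambda0", "mu0", "beta"),
  M4c = c("lambda0", "alpha", "epsilon"),
  M4d = c("lambda0", "alpha", "mu0", "beta"),
  M5  = "lambda0",
  M6  = c("lambda0", "alpha")
)

.MODEL_DESC <- c(
  M1  = "saturated diversity, constant turnover (Hey/Moran)",
  M2  = "saturated diversity, exponentially varying turnover",
  M3  = "expanding diversity, constant birth-death",
  M4a = "expanding diversity, varying speciation, constant extinction",
  M4b = "expanding diversity, constant speciation, varying extinction",
  M4c = "expanding diversity, varying rates, constant extinction fraction",
  M4d = "expanding diversity, independently varying rates",
  M5  = "expanding diversity, pure birth (Yule)",
  M6  = "expanding diversity, varying speciation, no extinction"
)

# threshold below which an exponential-variation coefficient is treated as
# zero (constant-rate limit) to avoid catastrophic cancellation
.COEF_EPS <- 1e-8

#' Table of the nine diversification models
#'
#' Returns a data frame describing the nine diversification scenarios the
#' package implements: model identifier, number of free parameters, the
#' parameter names, and which side of each hypothesis partition the model
#' belongs to (expanding vs saturated diversity, time-varying vs constant
#' rates, extinction present vs absent).
#'
#' @return A data frame with one row per model.
#' @examples
#' diversification_models()
#' @export
diversification_models <- function() {
  data.frame(
    model = .MODEL_IDS,
    k = vapply(.MODEL_PARAMS[.MODEL_IDS], length, integer(1)),
    parameters = vapply(.MODEL_PARAMS[.MODEL_IDS], paste, character(1),
                        collapse = ", "),
    description = unname(.MODEL_DESC[.MODEL_IDS]),
    expanding  = .MODEL_IDS %in% c("M3", "M4a", "M4b", "M4c", "M4d", "M5", "M6"),
    varying    = .MODEL_IDS %in% c("M2", "M4a", "M4b", "M4c", "M4d", "M6"),
    extinction = .MODEL_IDS %in% c("M1", "M2", "M3", "M4a", "M4b", "M4c", "M4d"),
    row.names = NULL
  )
}

#' Specify a diversification model
#'
#' Constructs a model specification: one of the nine diversification
#' scenarios together with its parameter values and the present-day clade
#' richness `N0`.
#'
#' The scenarios are: `M1` (saturated diversity, constant turnover rate
#' `tau0`; the Hey/Moran model), `M2` (saturated diversity, turnover
#' `tau0*exp(gamma*t)`), `M3` (constant-rate birth-death with speciation
#' `lambda0` and extinction `mu0`), `M4a` (speciation `lambda0*exp(alpha*t)`,
#' constant extinction `mu0`), `M4b` (constant speciation, extinction
#' `mu0*exp(beta*t)`), `M4c` (speciation `lambda0*exp(alpha*t)`, extinction a
#' fixed fraction `epsilon` of speciation), `M4d` (speciation and extinction
#' varying independently), `M5` (pure-birth Yule with rate `lambda0`) and
#' `M6` (speciation `lambda0*exp(alpha*t)`, no extinction).
#'
#' Time `t` is measured backwards from the present, so a positive variation
#' coefficient (`alpha`, `beta`, `gamma`) means the rate decays towards the
#' present.
#'
#' @param model Model identifier, one of `"M1"`, `"M2"`, `"M3"`, `"M4a"`,
#'   `"M4b"`, `"M4c"`, `"M4d"`, `"M5"`, `"M6"`.
#' @param ... Named model parameters (see Details); exactly the parameters
#'   of the chosen model must be supplied.
#' @param N0 Present-day species richness of the clade (must be >= 2).
#' @return An object of class `"model_spec"`.
#' @examples
#' diversification_model("M3", lambda0 = 1, mu0 = 0.5, N0 = 100)
#' diversification_model("M6", lambda0 = 0.6, alpha = 0.4, N0 = 250)
#' @export
diversification_model <- function(model, ..., N0) {
  model <- match.arg(model, .MODEL_IDS)
  pars <- list(...)
  wanted <- .MODEL_PARAMS[[model]]
  if (!setequal(names(pars), wanted))
    stop(sprintf("model %s takes parameters {%s}, got {%s}", model,
                 paste(wanted, collapse = ", "),
                 paste(names(pars), collapse = ", ")))
  pars <- vapply(pars[wanted], function(p) as.numeric(p)[1], numeric(1))
  if (!is.numeric(N0) || length(N0) != 1 || !is.finite(N0) || N0 < 2)
    stop("N0 must be a single finite number >= 2")
  rate_names <- intersect(names(pars), c("tau0", "lambda0", "mu0"))
  if (any(pars[rate_names] < 0))
    stop("rates at present (tau0, lambda0, mu0) must be >= 0")
  if ("epsilon" %in% names(pars) &&
      (pars[["epsilon"]] < 0 || pars[["epsilon"]] > 1))
    stop("epsilon must lie in [0, 1]")
  if (model == "M3" && pars[["mu0"]] > pars[["lambda0"]])
    stop("M3 requires mu0 <= lambda0 (speciation >= extinction at all times)")
  structure(list(model = model, params = pars, N0 = as.numeric(N0)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Diversification model ", x$model, ": ", .MODEL_DESC[[x$model]], "\n",
      sep = "")
  cat("  parameters: ",
      paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  cat("  present-day richness N0 =", format(x$N0), "\n")
  invisible(x)
}

#' Speciation and extinction rates at a time before present
#'
#' Evaluates the per-lineage speciation rate lambda(t) and extinction rate
#' mu(t) of a model at times `t` before present.  For the saturated-
#' diversity models M1 and M2 both rates equal the turnover rate tau(t)
#' (every extinction is immediately compensated by a speciation).
#'
#' @param spec A [diversification_model()] object.
#' @param t Numeric vector of times before present (>= 0).
#' @return A list with numeric components `speciation` and `extinction`,
#'   each of the same length as `t`.
#' @examples
#' m <- diversification_model("M6", lambda0 = 6, alpha = 0.25, N0 = 100)
#' rates_at(m, c(0, 1, 2))
#' @export
rates_at <- function(spec, t) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(t < 0)) stop("t must be >= 0 (time before present)")
  p <- as.list(spec$params)
  switch(spec$model,
    M1 = {
      lam <- rep(p$tau0, length(t))
      list(speciation = lam, extinction = lam)
    },
    M2 = {
      lam <- p$tau0 * exp(p$gamma * t)
      list(speciation = lam, extinction = lam)
    },
    M3 = list(speciation = rep(p$lambda0, length(t)),
              extinction = rep(p$mu0, length(t))),
    M4a = list(speciation = p$lambda0 * exp(p$alpha * t),
               extinction = rep(p$mu0, length(t))),
    M4b = list(speciation = rep(p$lambda0, length(t)),
               extinction = p$mu0 * exp(p$beta * t)),
    M4c = {
      lam <- p$lambda0 * exp(p$alpha * t)
      list(speciation = lam, extinction = p$epsilon * lam)
    },
    M4d = list(speciation = p$lambda0 * exp(p$alpha * t),
               extinction = p$mu0 * exp(p$beta * t)),
    M5 = list(speciation = rep(p$lambda0, length(t)),
              extinction = rep(0, length(t))),
    M6 = list(speciation = p$lambda0 * exp(p$alpha * t),
              extinction = rep(0, length(t)))
  )
}

# integral of an exponentially varying rate: int_0^t r0 * exp(c*s) ds,
# with the constant-rate limit for |c| below .COEF_EPS
.exp_rate_integral <- function(r0, cc, t) {
  if (abs(cc) < .COEF_EPS) r0 * t else (r0 / cc) * expm1(cc * t)
}

# H(t) = int_0^t [lambda(s) - mu(s)] ds (net diversification integral),
# vectorized over t
.net_integral <- function(spec, t) {
  p <- as.list(spec$params)
  switch(spec$model,
    M1 = ,
    M2 = rep(0, length(t)),
    M3 = (p$lambda0 - p$mu0) * t,
    M4a = .exp_rate_integral(p$lambda0, p$alpha, t) - p$mu0 * t,
    M4b = p$lambda0 * t - .exp_rate_integral(p$mu0, p$beta, t),
    M4c = (1 - p$epsilon) * .exp_rate_integral(p$lambda0, p$alpha, t),
    M4d = .exp_rate_integral(p$lambda0, p$alpha, t) -
          .exp_rate_integral(p$mu0, p$beta, t),
    M5 = p$lambda0 * t,
    M6 = .exp_rate_integral(p$lambda0, p$alpha, t)
  )
}

#' Deterministic expected diversity through time
#'
#' Evaluates the deterministic expectation N(t) of clade size at time `t`
#' before present: `N(t) = N0` under the saturated-diversity models (M1,
#' M2) and `N(t) = N0 * exp(-int_0^t [lambda(s) - mu(s)] ds)` otherwise,
#' using the closed form of the integral for each model.  Variation
#' coefficients with magnitude below `1e-8` are evaluated in the
#' constant-rate limit to avoid cancellation.
#'
#' @inheritParams rates_at
#' @return Numeric vector of expected species numbers, same length as `t`.
#' @examples
#' m <- diversification_model("M5", lambda0 = log(2), N0 = 100)
#' expected_diversity(m, 1)  # 50: diversity doubled over the last time unit
#' @export
expected_diversity <- function(spec, t) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(t < 0)) stop("t must be >= 0 (time before present)")
  spec$N0 * exp(-.net_integral(spec, t))
}

#' Check that speciation dominates extinction over a time window
#'
#' The coalescent likelihood is valid only if lambda(t) >= mu(t) for all t
#' in `[0, horizon]`.  Because every model's rates are single exponentials
#' in t, the log-rate difference is linear in t, so checking the two
#' endpoints is exact; a dense-grid check can be requested as a
#' belt-and-braces alternative.
#'
#' @inheritParams rates_at
#' @param horizon Upper end of the time window (typically the root age of
#'   the tree under analysis).
#' @param grid_points If > 0, additionally check on a regular grid of this
#'   many points across the window.
#' @return `TRUE` if lambda(t) >= mu(t) throughout, else `FALSE` (never
#'   raises for parameter values that merely violate the constraint).
#' @examples
#' m <- diversification_model("M4a", lambda0 = 1, alpha = -0.5, mu0 = 0.5,
#'                            N0 = 100)
#' validate_constraint(m, horizon = 2)  # FALSE: lambda(2) < mu(2)
#' @export
validate_constraint <- function(spec, horizon, grid_points = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.finite(horizon) || horizon < 0) return(FALSE)
  ts <- c(0, horizon)
  if (grid_points > 0) ts <- c(ts, seq(0, horizon, length.out = grid_points))
  r <- rates_at(spec, ts)
  all(r$speciation >= r$extinction)
}
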