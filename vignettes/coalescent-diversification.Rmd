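---
title: "Inferring diversification dynamics with a coalescent likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring diversification dynamics with a coalescent likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldiv)
```

## The model

`coaldiv` treats a clade of species the way population genetics treats a
population of individuals.  An ultrametric phylogeny of $n$ species sampled
from a clade of present-day richness $N_0$ is read backwards in time: while
$j$ sampled lineages coexist, they coalesce (two lineages find their common
ancestor) at rate

$$\rho_j(t) \;=\; \kappa\,\binom{j}{2}\,\frac{\lambda(t)}{N(t)},$$

where $\lambda(t)$ is the per-lineage speciation rate at time $t$ before
present, $N(t)$ the deterministic expectation of clade size, and $\kappa$ a
convention constant discussed below.  The form follows the classical
coalescent in a population of deterministically varying size: the pair
rate is $1/N$ per generation, and the generation time for a clade — the
time for a complete turnover of species — is $1/\lambda(t)$, so that a
change of variable to real time multiplies the Kingman rate by
$\lambda(t)$.

Numbering internal nodes $1,\dots,n-1$ from the root towards the tips,
with depths $t_1 > \dots > t_{n-1}$ and internode distances
$g_j = t_{j-1} - t_j$ (exactly $j$ lineages exist during $g_j$), the
log-likelihood of the $n-2$ internode distances is

$$\ell \;=\; \sum_{j=2}^{n-1}\Big[\log \rho_j(t_{j-1})
  \;-\; \int_{t_j}^{t_{j-1}} \rho_j(s)\,ds\Big].$$

The terminal interval $t_{n-1}$ (most recent node to present) is not a
waiting time between cladogenesis events and contributes no factor: the
likelihood conditions on $n$ and on $t_{n-1}$.  Incomplete sampling is
automatic — the $n$ tips are simply a coalescent sample from the $N_0$
extant species — which is the practical advantage of the backwards-time
formulation over forward-time birth–death likelihoods.

The expression is valid only when $\lambda(t) \ge \mu(t)$ everywhere in
the window (diversity non-decreasing towards the present).  Parameter
sets violating this are given log-likelihood $-\infty$, not an error, so
optimizers can traverse them.

### The nine scenarios

`diversification_models()` lists the candidate set.  Two saturated-
diversity models keep $N(t) = N_0$: every extinction is immediately
balanced by a speciation at turnover rate $\tau(t)$ — constant (`M1`,
the Hey/Moran model) or exponentially varying (`M2`).  Seven expanding-
diversity models set
$N(t) = N_0\exp\!\big(-\int_0^t[\lambda(s)-\mu(s)]ds\big)$: the
constant-rate birth–death `M3`, four flavours with exponentially varying
rates (`M4a`–`M4d`), the Yule model `M5`, and `M6` with varying
speciation and no extinction.  Time is measured backwards, so a positive
variation coefficient ($\alpha$, $\beta$, $\gamma$) means the rate was
higher in the past.  Exponential variation is the only time dependence
implemented; the machinery would accept any integrable form.

### The $\kappa$ convention

The package default is $\kappa = 2$, calibrated against the Moran-type
turnover simulator rather than chosen by convention.  In that simulator,
turnover events occur at total rate $N\tau$ and each event kills one
uniformly chosen lineage and bifurcates another; a given pair of
lineages merges with probability $2/[N(N-1)]$ per event, hence a pair
coalescence rate of $2\tau/N$ per unit time — twice the Wright–Fisher
Kingman rate at generation time $1/\tau$.  Two package tests pin this
down empirically: the distribution of pair-MRCA depths in simulated
trees is exponential with rate $2\tau_0/N_0$ (Kolmogorov–Smirnov), and
the maximum-likelihood $\hat\tau_0$ on simulated trees is unbiased to
within a few percent only under $\kappa = 2$.  Because $\kappa$
multiplies every $\rho_j$ equally, it shifts absolute rate estimates by
a constant factor and cancels exactly from all AICc comparisons,
weights, and hypothesis probabilities.

## Fitting and model selection

```{r example, eval = FALSE}
st  <- simulate_saturated(N0 = 100, tau0 = 1, seed = 5)
tr  <- sample_tips(st, f = 0.75)           # incomplete sampling
cmp <- compare_models(coalescent_times(tr), N0 = 100, seed = 9)
cmp
plot(cmp)
```

`fit_model()` maximizes $\ell$ by multi-start Nelder–Mead on transformed
parameters: rates on the log scale, variation coefficients untransformed,
and the extinction fraction $\varepsilon = \mu/\lambda$ on the logit
scale (`M3` is parameterized internally as
$(\lambda_0, \varepsilon)$ so the $\lambda \ge \mu$ constraint holds by
construction).  Ten starts are used by default: a heuristic start — the
closed-form constant-turnover MLE
$\hat\tau_0 = (n-2)N_0 / (\kappa \sum_j \binom{j}{2} g_j)$ sets the rate
scale for saturated models, and the net rate $r_0 = \log(N_0/2)/t_1$
(carrying the clade from two species at the root to $N_0$) sets it for
expanding ones — plus randomized restarts.  One-parameter models use
Brent's method on a wide bracket instead, since one-dimensional
Nelder–Mead is unreliable.  `compare_models()` additionally warm-starts
every model from the optima of its fitted nested submodels, which
guarantees the nesting inequality
$\max_\theta \ell_{\text{large}} \ge \max_\theta \ell_{\text{small}}$
that plain multi-start optimization can miss on deep saturated trees.

Goodness of fit is scored with the small-sample Akaike criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n_{\text{obs}}-k-1)$ with
$n_{\text{obs}} = n-2$ internode distances, and support with Akaike
weights $w_l \propto \exp(-\Delta_l/2)$.  Three hypothesis partitions
are evaluated by the best-in-subset rule: within each side (expanding
vs saturated diversity; varying vs constant rates; extinction present vs
absent) the lowest-AICc model is selected and the two winners' weights
are renormalized.  The extinction fraction at present is 1 for `M1`/`M2`
(every speciation is tied to an extinction), 0 for `M5`/`M6`, and
$\hat\mu(0)/\hat\lambda(0)$ otherwise.  Exact AICc ties go to the model
with fewer parameters, then to the fixed model order.  Models that
cannot be fitted at all (too few tips for their parameter count) are
kept in the table with $\mathrm{AICc} = +\infty$ and weight 0.

## Simulators: what they emulate, and what they do not

`simulate_saturated()` implements the Moran-type scheme: $N_0$ lineages
joined by an artificial root polytomy, turnover events at total rate
$N_0\tau(t)$ with exponential waiting times evaluated at the previous
event, one uniformly chosen victim and one uniformly chosen parent per
event.  The polytomy disappears once all but one founding lineage has
died; the default run length $10\,N_0/\tau_0$ is about ten times the
expected time to the sample MRCA, and the duration doubles (up to three
times) if the polytomy persists, after which the tree is returned
flagged.  `simulate_birth_death()` starts from a single lineage with
events at total rate $N_{\text{cur}}(\lambda + \mu)$, bifurcation with
probability $\lambda/(\lambda+\mu)$; extinct-clade replicates are
discarded and resimulated (conditioning on survival).  Both return the
reconstructed tree of extant species, which is exactly ultrametric.

Two fidelity caveats are deliberate.  Waiting times use the total rate
at the previous event rather than exact thinning of the inhomogeneous
process — exact for constant rates, and accurate when per-event rate
changes are small, as they are for the parameter ranges used here.  And
the likelihood approximates the stochastic clade size by its
deterministic expectation $N(t)$; the simulators do not, which is
precisely why parameter-recovery experiments are informative.  Neither
simulator (nor the likelihood) includes across-lineage rate
heterogeneity, non-random taxon sampling, or diversity declines, so
passing tests say nothing about robustness to those features of real
data.

## Numerical choices

* Integrals $\int \lambda(s)/N(s)\,ds$ have closed forms for `M1`,
  `M2`, `M3`, `M4c`, `M5`, `M6`, written with `expm1` to avoid
  cancellation on short intervals.  `M4a`, `M4b`, `M4d` use vectorized
  Gauss–Legendre panels per internode interval: `cumulative_rate()`
  compares orders 21 and 43 and falls back to adaptive
  `stats::integrate` (rel. tol. $10^{-12}$) on disagreement; the
  optimizer hot path uses a single order-25 panel, which tests hold to
  $10^{-6}$ of a brute-force trapezoid oracle and $\sim 10^{-7}$ of the
  checked path.
* Variation coefficients with $|\alpha| < 10^{-8}$ switch to the
  constant-rate limit expressions.
* $N(t)$ underflow or rate overflow yields $\ell = -\infty$ (penalized,
  with a slope back towards the heuristic start inside the optimizer).
* The $\lambda \ge \mu$ check is exact from the interval endpoints: all
  nine models have pure-exponential rates, so the log-rate difference is
  linear in $t$; a dense-grid check is available via `grid_points`.
* Ultrametricity is validated to a relative tolerance of $10^{-4}$ of
  tree depth by default (empirical chronograms carry rounding noise);
  the tolerance is configurable.
* Polytomies are resolved by random bifurcations spaced $10^{-6}$ time
  units apart, the conventional treatment for contentious nodes.  The
  new nodes of a polytomy are stacked at $\varepsilon, 2\varepsilon,
  \dots$ below it regardless of the random topology drawn, so every
  resolution yields the same multiset of internode distances and
  internode-distance likelihoods are exactly invariant to the order of
  resolution.  Pre-existing zero-length internal edges (tied depths) are
  spaced out the same way; ties are never perturbed silently elsewhere.
* Zero-length terminal branches are legal — they never enter the
  likelihood.

## Study conditions used by the tests and the acceptance script

The package's experiments run at desk scale, sized to finish in minutes
on one CPU; the conditions are fixed once and reported here.

* **Classification experiment**: 100 phylogenies under `M1`
  ($N_0 = 100$, $\tau_0 = 1$ — any rate works, classification is
  invariant to time rescaling), subsampled at $f = 0.75$, all nine
  models fitted.  Counts of saturated-diversity winners, constant-rate
  winners, and `M1`/`M2` winners are compared with the reference values
  within twice the binomial standard error.  `scripts/acceptance.R`
  reruns exactly this experiment from scratch.
* **Decaying-speciation detection and parameter recovery**: trees
  simulated under `M4a` with $\lambda_0 = 0.6$, $\alpha = 0.4$,
  $\mu_0 = 0.3$, duration $4.25$, conditioned on $\ge 60$ survivors
  (median clade $\sim 200$ species; the speciation rate decays
  five-fold across the window and stays above $\mu$ throughout, and an
  $f = 0.1$ subsample still leaves a usable tree).  Recovery runs 200
  replicates at $f \in \{0.1, 0.75, 1\}$ fitting the generating model
  with three optimizer starts (the true-model fit converges readily;
  restart-spread diagnostics sit near zero).
* **Gamma calibration**: $10^4$ Yule genealogies of 50 tips generated
  directly in interval representation ($g_j \sim
  \mathrm{Exp}(j\lambda)$, $j = 2..n$, the exact Yule internode law),
  checking mean $\approx 0$ and s.d. $\approx 1$.
* **$\kappa$ calibration**: pair-MRCA depths from the turnover
  simulator at $N_0 = 10$ against $\mathrm{Exp}(2\tau_0/N_0)$, and
  median relative bias of $\hat\tau_0$ under $\kappa = 2$ on
  $f = 0.75$ subsamples of $N_0 = 100$ trees, required below 5%.

## Known limitations

* $N_0$ must be supplied: the likelihood involves only ratios
  $\lambda/N$, so clade size cannot be estimated from the tree.
* Extinction parameters are weakly identified on single trees of a few
  hundred tips; expect wide quantile bands and a mild upward bias of
  $\hat\mu_0$ (visible in the package's own recovery experiment).
* No confidence intervals on parameters — uncertainty is only
  quantified across simulation replicates, and model-selection
  uncertainty through Akaike weights.
* Non-ultrametric (serially sampled) trees, lineage-specific rates,
  diversity declines and mass extinctions are out of scope.
* The gamma statistic is computed without any correction for incomplete
  sampling; on subsampled trees it is biased downward, which is itself
  one of the patterns the coalescent likelihood accommodates and the
  summary statistic does not.
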