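# coaldiv

Coalescent inference of diversification dynamics from molecular
phylogenies.

## The problem

Given an ultrametric phylogeny of `n` species sampled from a clade with
`N0` extant species, what kind of diversification process produced it?
Is diversity saturated (every extinction balanced by a speciation) or
still expanding?  Are speciation/extinction rates constant or do they
change through time?  Does extinction leave a detectable signal?

`coaldiv` answers these questions by reading the phylogeny backwards in
time, like a coalescent genealogy.  While `j` sampled lineages coexist
they coalesce at rate

    rho_j(t) = kappa * C(j,2) * lambda(t) / N(t)

where `lambda(t)` is the speciation rate, `N(t)` the deterministic
expected clade size at time `t` before present, and `kappa` a convention
constant (the package default 2 matches the Moran-type turnover
simulator; it cancels from all model comparisons).  The log-likelihood
of the `n - 2` internode distances `g_j = t_{j-1} - t_j` is

    logL = sum_{j=2}^{n-1} [ log rho_j(t_{j-1}) - int_{t_j}^{t_{j-1}} rho_j(s) ds ]

conditioning on `n` and on the depth of the most recent node (the
terminal interval is not a waiting time between speciation events).
Because a coalescent is by nature a theory of samples, incomplete taxon
sampling (`n < N0`) is handled with no extra machinery.

Nine diversification scenarios are compared: saturated diversity with
constant (`M1`, Hey/Moran) or exponentially varying (`M2`) turnover;
expanding diversity with constant rates (`M3`, birth-death; `M5`, Yule)
or exponentially varying speciation and/or extinction (`M4a`-`M4d`,
`M6`).  Models are fitted by multi-start maximum likelihood, scored by
the small-sample AICc, and summarized by Akaike weights, best-in-subset
hypothesis probabilities (expanding vs saturated, varying vs constant,
extinction vs none) and the extinction fraction at present.

The package is aimed at macroevolution researchers with a chronogram, a
clade-richness estimate, and the usual worry that their tree contains
only a fraction of the clade's species.

## Worked example

Simulate a saturated-diversity clade of 100 species, sample 75% of them,
and ask which scenario explains the tree:

```r
library(coaldiv)

st  <- simulate_saturated(N0 = 100, tau0 = 1, seed = 5)
tr  <- sample_tips(st, f = 0.75)
cmp <- compare_models(coalescent_times(tr), N0 = 100, seed = 9)
cmp
#> Coalescent diversification model comparison (75 tips, N0 = 100)
#>
#>  model k      logL      AICc    delta weight
#>     M1 1   66.2972 -130.5380   0.0000 0.4439
#>     M2 2   66.5841 -128.9967   1.5413 0.2054
#>     M3 2   66.2972 -128.4230   2.1151 0.1542
#>    M4c 3   66.5841 -126.8203   3.7177 0.0692
#>    M4b 3   66.2972 -126.2465   4.2915 0.0519
#>    M4a 3   66.2972 -126.2465   4.2915 0.0519
#>    M4d 4   66.6214 -124.6547   5.8834 0.0234
#>     M6 2   40.9655  -77.7595  52.7785 0.0000
#>     M5 1 -114.8640  231.7844 362.3224 0.0000
#>
#> Best model: M1 - saturated diversity, constant turnover (Hey/Moran)
#> P(expanding diversity) = 0.258   P(time-varying rates) = 0.316   P(extinction) = 1.000
#> Extinction fraction at present (best model): 1.000
```

The true generating model (`M1`) wins; the hypothesis probabilities read
off the same story (diversity saturated, rates constant, extinction
certain — in a saturated model every speciation is tied to an
extinction, so the fraction is 1 by construction).  `tau0` is estimated
at `0.81` (`coef(cmp$fits$M1)`), against a truth of 1 - a typical
single-tree spread; the calibration tests pin the median bias below 5%.

On an empirical tree, replace the simulated input:

```r
tr  <- read_newick("mytree.nwk")          # validates ultrametricity
tr  <- resolve_polytomies(tr)             # 1e-6 spacing, if needed
cmp <- compare_models(coalescent_times(tr), N0 = 230)   # known richness
plot(cmp)                                  # Akaike-weight profile
gamma_statistic(tr)                        # node-depth summary
venditti_model_selection(tr)               # branch-length-distribution comparator
```

A thin command-line interface with the same functionality is installed
at `inst/cli/coaldiv` (`coaldiv stats`, `coaldiv fit`,
`coaldiv simulate`).

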