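Package: coaldiv
Title: Coalescent Inference of Diversification Dynamics from Molecular
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the dynamics of diversification from ultrametric
    molecular phylogenies using a coalescent (backwards-time) likelihood of
    internode distances.  Nine birth-death and turnover scenarios are
    supported, with constant or exponentially time-varying speciation,
    extinction and turnover rates, saturated or expanding diversity, and
    incomplete taxon sampling.  Models are fitted by multi-start maximum
    likelihood and compared with the second-order Akaike Information
    Criterion (AICc) and Akaike weights; the extinction fraction at present
    is estimated from the best-fitting model.  Forward-time simulators
    (a Moran-type turnover process for saturated diversity and a
    time-inhomogeneous birth-death process for expanding diversity) allow
    parameter-recovery and model-classification experiments, and summary
    statistics (gamma statistic, branch-length distribution fits) permit
    comparison with alternative inference approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
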