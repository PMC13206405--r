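Package: cbsl
Title: Constraint-Based Structure Learning with Hierarchical Gaussian Filter Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for online structure learning by an ensemble of
    Hierarchical Gaussian Filter (HGF) learning components whose updates are
    gated by system-level constraint satisfaction. Components are born anchored
    on incoming observations, compete through a normalised activity
    distribution, carry continuous weights updated towards their activity, and
    are pruned when their weight falls below a threshold. Includes the Gaussian
    mixture environments used to study the model, a frozen-model behavioural
    test procedure, evaluation measures (adjusted Rand index, exact
    mixture-Wasserstein distance via a transportation simplex, component
    counts), a perfect-agent benchmark, and a reproducible experiment harness
    for baseline distributions, parameter sweeps and span-perturbation
    trajectory studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
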