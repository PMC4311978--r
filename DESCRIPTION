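Package: sirm
Title: Probabilistic Connectivity-Based Parcellation with the Streamline
    Infinite Relational Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonparametric Bayesian parcellation of structural brain
    networks. A Chinese-restaurant-process prior over partitions is combined
    with a Beta-Bernoulli stochastic block model for latent binary
    connectivity and a Dirichlet-compound-multinomial forward model linking
    connectivity to probabilistic-tractography streamline counts. A block
    Gibbs sampler jointly infers a partition shared across subjects and
    per-subject connectomes, quantifies parcellation uncertainty through
    co-assignment probabilities and credible intervals on the number of
    clusters, and provides evaluation statistics (adjusted mutual
    information, within-cluster streamline ratios).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
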