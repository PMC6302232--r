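Package: infodemics
Title: Disease Surveillance from Social-Media Message Volume and Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing disease-related
    message volume and content on short-message social media. Messages are
    filtered against consumer-health keyword lexica, keyword precision is
    estimated from annotated samples and used to derive corrected per-disease
    message counts, messages are mapped to counties from coordinates or
    free-text profile locations under a population-concentration rule,
    latent Dirichlet allocation (collapsed Gibbs sampling) derives topics,
    nonnegative matrix factorization clusters topics into themes, and
    disease-content association is quantified by point-biserial correlation
    with Benjamini-Hochberg false-discovery-rate control and by pointwise
    mutual information. Claims-based county prevalence is computed for
    comparison against corrected message volume. A synthetic-corpus
    generator with full ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    stringi
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
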