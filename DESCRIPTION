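Package: toxprofiler
Title: Mechanism Profiling of Oxidative-Stress Hepatotoxicity from qHTS Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a three-stage workflow for
    profiling hepatotoxicity mechanisms driven by oxidative stress:
    quantitative high-throughput screening (qHTS) concentration-response
    processing into CurveP fingerprints and four-level activity calls;
    bioassay-profile mining of a compound-by-assay response matrix with
    sensitivity/specificity/CCR, a likelihood parameter L, rate-of-actives
    (RA) scoring and chi-squared in vitro-in vivo correlation (IVIVC)
    tests; consensus QSAR modeling of antioxidant response element (ARE)
    pathway activation with similarity-guided down-sampling, two consensus
    prediction thresholds and a k-nearest-neighbor applicability domain;
    and toxicophore-subset IVIVC evaluation with circular-fragment
    enrichment ranking. A synthetic-data module generates compound
    libraries, Hill-shaped qHTS curves, sparse assay matrices and in vivo
    labels with planted ground truth so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
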