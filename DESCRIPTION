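Package: cstdyn
Title: Community State Type Dynamics in Longitudinal Multi-Site Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying coordinated microbiota development across body
    sites in longitudinal infant cohorts. Clusters per-site OTU count tables
    into community state types (CSTs) with Dirichlet-Multinomial mixture
    models selected by subsampled Laplace evidence; models CST occurrence over
    infant maturity with penalized smooths and a single-index model combining
    week of life and gestational age at birth; classifies CSTs into
    chronological, convergent and idiosyncratic occurrence patterns; tests
    cross-site CST co-occurrence, per-taxon mixed-model associations with
    remote-site CSTs under FDR control, and shared-OTU residual correlations;
    and estimates cross-site canonical correlations with subject-blocked
    cross-validation before and after removing temporal structure. Includes a
    synthetic longitudinal cohort generator with known ground truth so every
    stage is testable without external data, and a deterministic pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    mgcv,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    biomformat
Config/testthat/edition: 3
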