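Package: rsnlong
Title: Longitudinal Resting-State Network Outcome Measures and Their
    Temporal Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of densely sampled longitudinal resting-state
    fMRI studies in a single subject.  Derives network outcome measures by
    group independent component analysis (two-stage PCA reduction with minimum
    description length order selection, extended Infomax ICA with a stability
    screen, and GICA3 backreconstruction): spatial-map similarity (eta-squared),
    temporal fluctuation magnitude (RMS percent signal change), and
    between-network connectivity.  Summarises their week-to-week
    reproducibility (coefficient of variation, equal-variance F-tests with
    multiplicity correction) and characterises their temporal structure on an
    irregular weekly calendar: linear trend, annual periodicity by a
    regression-based spectral estimate with Fisher's exact g-test, covariate
    correlation with permutation inference, and ARMA persistence models fitted
    by a long-autoregression with Durbin's reduced-statistics method, robust to
    missing weeks.  Includes a synthetic-data module that generates session
    calendars, toy 4D volumes with known sources, outcome series with known
    trend/seasonality/ARMA structure, motion tables, and phantom and
    temperature series, with full ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
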