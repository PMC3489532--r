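Package: psmix
Title: Mixture-Model Confidence Estimation for Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns statistical confidence to database-search
    peptide-spectrum matches (PSMs) with two-component mixture models fit by
    expectation-maximization. A Normal component models correctly identified
    spectra and a shifted-Gamma or Gumbel component models incorrect ones;
    optional discrete factors (tryptic termini, missed cleavages, mass error)
    refine the posteriors. Variants include a semisupervised fit that pins
    decoy matches to the incorrect component, a semiparametric fit that
    replaces the parametric components with decoy-anchored kernel density
    estimates, and an adaptive refit of the linear discriminant that combines
    raw search-engine scores, with rescoring of lower-ranked candidate
    matches. Provides posterior error probabilities, p-values, false
    discovery rate estimators (model-based, mean-PEP, and target-decoy),
    q-values, bootstrap stability diagnostics, and a synthetic PSM generator
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
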