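Package: specscreen
Title: Spectrum-Effect Relationship Screening for Herbal Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spectrum-effect relationship chemometrics on
    chromatographic fingerprint peak tables: pharmacodynamic scoring and
    positive transformation, analytic-hierarchy-process and entropy-weight
    multi-criteria weighting with composite efficacy scores, three
    correlation engines (Pearson screening, grey relational analysis, and
    NIPALS OPLS with VIP, cross-validated Q2 and permutation testing),
    three-way consensus intersection, and centrality-based prioritisation
    of candidate bioactive constituents on a herb-constituent-indicator
    network.  Includes a synthetic fingerprint-efficacy data generator
    with planted actives for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
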