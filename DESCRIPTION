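Package: strainenv
Title: Growth-Coupled Strain Design from Production Envelopes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Target-point guided design of growth-coupled production strains
    from constraint-based metabolic models. Reads SBML Level 3 (FBC) and
    BiGG-style JSON models, converts them to irreversible form, computes
    product-versus-growth production envelopes by repeated linear
    programming, finds the minimal set of active reactions supporting a
    user-chosen target point with a mixed-integer linear program, shrinks
    the implied knockout set by sequential reinsertion, scans interior
    target points for alternative envelopes, and solves a duality-based
    bilevel program to bound the number of knockouts. Ships a dense
    bounded-variable simplex and branch-and-bound solver so the whole
    pipeline runs without external optimisers; an optional 'scipy'/HiGHS
    backend is available for genome-scale models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
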