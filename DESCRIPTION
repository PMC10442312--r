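Package: sictf
Title: Patient-Zero Identification via Adaptive Contact Tracing Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well the source of an epidemic (patient
    zero) can be recovered when the contact network is initially unknown and
    must be explored through contact tracing queries. Implements a household
    configuration-model contact network, a discrete-day epidemic simulator
    with asymptomatic and hospitalized disease courses, a query oracle that
    enforces detection at the first hospitalization, next-day test results
    and a daily testing budget, the LocalSearch (LS) and LS+ adaptive
    source-identification algorithms with query-cost accounting, an adaptive
    Size-Gain baseline, closed-form theory for the source-identification
    probability on red-blue tree approximations (random exponential tree
    profiles, stopped deterministic-tree path-length laws), and a seeded
    experiment runner that validates the theory against simulation with
    Wilson score intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
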