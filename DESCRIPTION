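Package: cariescua
Title: Markov Cohort Cost-Utility Analysis of Annual Preventive Dental Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model for an annual school-based
    preventive dental intervention in a remote community, compared with usual
    care. A three-state Markov cohort model (no active caries, active caries,
    caries untreated) is run over a ten-year horizon with annual cycles to
    estimate discounted costs, quality-adjusted life years (QALYs) and caries
    lesions per arm, the incremental cost-effectiveness ratio and net monetary
    benefit. Includes one-way deterministic sensitivity analysis with tornado
    ordering, named scenario analyses, two-way validation grids, probabilistic
    sensitivity analysis with beta, gamma and triangular distributions fitted
    from interval bounds, and a synthetic individual-level data generator that
    emulates the two-arm, two-year caries-incidence follow-up from which the
    model inputs are estimated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
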