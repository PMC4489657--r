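Package: proturn
Title: Protein Turnover Kinetics with Time-Varying Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the abundance of an unstable regulatory protein as the
    balance between synthesis and first-order proteolysis with a
    time-varying degradation rate, dP/dt = ks - kd(t) P.  Provides numerical
    and closed-form solutions of the turnover equation, half-life estimation
    from translation shut-off (chase) assays with censored reporting,
    relative least-squares fitting of the degradation acceleration,
    point-wise inference of the synthesis rate from abundance time courses,
    translation-rate estimation by mRNA normalization using comparative-Ct
    (delta-delta-Ct) qPCR quantification, and a seeded synthetic-data
    generator for growth curves, densitometry time courses, chase assays and
    Ct tables, so the whole inference chain can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
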