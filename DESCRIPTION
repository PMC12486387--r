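Package: mckm
Title: Multi Clone Kinetic Modelling of CHO Fed-Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic characterization of individual Chinese hamster
    ovary (CHO) cell line culture runs during cell line development. Implements
    an eight-state bolus fed-batch kinetic model (Monod growth on glucose,
    ammonium-driven death, Luedeking-Piret metabolite rates, and a
    glucose-gated lactate switch), per-run bounded least-squares estimation of
    the 13 kinetic parameters with automated parameter balancing, local
    sensitivity and collinearity-index identifiability analysis, a synthetic
    Ambr15-style campaign generator, and cohort summaries with Fisher linear
    discriminant analysis of fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
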