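Package: fixstep
Title: Fixation Dynamics and Stepwise Accumulation of Beneficial Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Diffusion-theory analysis of the fate of beneficial mutations in
    finite diploid populations, together with the extreme-value-theory
    distribution of beneficial fitness effects and Monte-Carlo accumulation of
    adaptive steps. Provides closed-form and quadrature fixation
    probabilities under dominant, semidominant, recessive and
    frequency-dependent selection, a finite-difference solver for mean
    conditional fixation times, a forward-time Wright-Fisher simulator used
    as an independent oracle, samplers and fitters for exponential
    beneficial-effect distributions and the combined occurrence-and-fixation
    ("improvement") distribution, and a synthetic-data generator emulating
    viral fitness-effect measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
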