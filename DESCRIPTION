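Package: contextval
Title: Simulation and Analysis of Context-Dependent Value Decoding Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing context-dependent value-based
    decision experiments of the kind used in multivariate fMRI studies of
    parallel value representation. Provides a constrained factorial design
    generator with trial-wise estimability (VIF) checks, a psychophysical
    staircase simulator, generative models of reaction times and accuracy
    with mixed-model comparison ladders, a synthetic multivoxel pattern
    generator with graded value codes and context-gated competition,
    cross-run noise-normalised representational similarity analysis,
    leave-one-run-out multinomial decoding with class balancing, and the
    neural-behavioural linking models that connect classifier read-outs to
    choice behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
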