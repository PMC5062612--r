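Package: rnselect
Title: Selection Index Theory for Reaction-Norm Genotype-by-Environment
    Interaction in Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic prediction of environment-specific accuracies of
    (genomic) estimated breeding values and responses to selection when a
    trait follows a linear reaction-norm model across a continuous
    environmental gradient. The gradient is discretized into environment
    classes under a standard-normal distribution, breeding goals are built
    from linear or diminishing-returns profit equations, and pseudo-BLUP
    selection indices (half-sib, progeny and genomic information, parental
    estimated breeding values, Bulmer equilibrium, finite-population
    selection intensities) are solved to compare sib-testing,
    progeny-testing and genomic breeding schemes, including their ability
    to change environmental sensitivity (resilience). A seeded
    individual-based Monte-Carlo simulator provides an independent check of
    the deterministic predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
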