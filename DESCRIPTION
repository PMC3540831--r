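Package: grnEvolve
Title: In Silico Evolution of Gap-Gene Circuits by Gene Cooption and
    Artificial Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of gene regulatory networks for
    Drosophila trunk gap-gene patterning. A one-dimensional gene-circuit
    reaction-diffusion model of gap genes under maternal Bicoid (and
    optionally Caudal) gradients is evolved by a genetic algorithm with
    truncation selection, logarithmic point mutation and one-point
    crossover, extended with gene-cooption operators (Gene Introduction
    and Withdrawal) and artificial-transposon operators (mark decay,
    cluster spread, host-to-host transmission). Includes a robustness
    measure against maternal-gradient variability with per-border
    precision analysis, a functional-involvement test for recruited
    genes, a host-transposon coevolution experiment, and a synthetic
    generator of FlyEx-like expression profiles so that all analyses run
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
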