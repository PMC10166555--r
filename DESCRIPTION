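Package: stochcrn
Title: Stochastic Logic with Chemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compiles Boolean truth tables into abstract chemical reaction
    networks (CRNs) that compute the corresponding stochastic logic function
    on values encoded fractionally by pairs of molecular species,
    x = [X1]/([X0]+[X1]).  Provides exact evaluation of the stochastic
    function as a multilinear polynomial, deterministic mass-action kinetics
    simulation of the compiled networks to input exhaustion, a randomized
    bitstream simulator serving as an independent sampling oracle, and
    rate-constant robustness sweeps that map the absolute output error over
    a lattice of input fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
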