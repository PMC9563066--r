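Package: quorumCA
Title: Cellular-Automaton Simulation of Quorum-Sensing-Coupled Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic cellular-automaton models of synthetic microbial
    consortia in which strain growth rates are coupled through diffusible
    signals. Acyl-homoserine-lactone (or metabolite) fields evolve by explicit
    forward-time central-space diffusion with first-order decay; cell-blocks
    divide probabilistically into empty von Neumann neighbours with a fitness
    that is Boolean-gated by the local concentration of the signal secreted by
    a coupled strain. Includes flux-balance-analysis tools to design reduced
    growth-rate single-gene-knockout strains from stoichiometric models, seed
    pattern generators, and reproducible in-silico assays: sender/receiver
    band-pass patterning, a preferential-growth assay with directional
    statistics, and parameter sweeps and grid searches over secretion rate,
    induction threshold and fitness gain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
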