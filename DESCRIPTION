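Package: plastomics
Title: Comparative Plastome Analysis: Structure, Repeats, Hotspots and Selection
Version: 0.1.0
Authors@R: person("Plastomics", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of circular chloroplast genomes
    (plastomes): detection of the quadripartite structure (LSC/IRb/SSC/IRa)
    and inverted-repeat junction gene contexts, inventories of simple
    sequence repeats, dispersed/palindromic and tandem repeats under
    REPuter/TRF-style parameters, a variable-sites percentage statistic for
    ranking mutational hotspots among homologous coding and intergenic
    regions, a Nei-Gojobori (1986) dN/dS screen for selective pressure, and
    a neighbor-joining marker-discrimination check.  Includes a simulator
    that generates quadripartite plastomes with planted repeats and evolves
    them along a phylogeny with region-specific rates, emitting
    machine-readable truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
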