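Package: capsidpath
Title: Local Assembly Rules and Packaging-Signal-Mediated Co-Assembly of
    T=1 Icosahedral Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models co-assembly of a T=1 icosahedral capsid (60 coat
    proteins) around a single-stranded RNA carrying 30 packaging signals,
    in the style of satellite tobacco necrosis virus. Builds the
    60-position capsid lattice with its nine symmetry-defined RNA moves
    and the mutual-exclusion pairing of binding sites, exhaustively
    enumerates pseudo-Hamiltonian RNA paths per move set with a compiled
    depth-first search, simulates packaging-signal-mediated assembly with
    the Gillespie algorithm, and optimises the 30 packaging-signal
    affinities for assembly yield with a genetic algorithm. Includes
    path-frequency classification of assembled capsids, fitness-landscape
    histograms, and tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
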