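Package: dryspike
Title: Single-Process Dry-Run Emulation of Distributed Spiking-Network
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and simulates one shard of a conceptually distributed
    spiking neuronal network simulation on a single process. Neurons are
    assigned to MPI-style ranks and threads by round-robin over global
    identifiers; spikes are exchanged once per minimum-delay interval
    through marker-structured send/receive buffers. In dry-run mode the
    remote ranks exist only conceptually and their input is emulated by
    fake spikes, either at a user-set target rate (static mode) or by
    replicating the local section of the spike buffer with re-randomised
    identifiers (dynamic mode). An emulated multi-rank mode serves as the
    validation oracle. Includes a balanced random network generator with
    optional spike-timing dependent plasticity, firing-rate and
    interspike-interval statistics, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
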