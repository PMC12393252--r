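Package: fishprobes
Title: Thermodynamic, Expression-Aware Design of Single-Molecule RNA-FISH
    Probe Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Designs and evaluates oligonucleotide probe sets for
    single-molecule RNA fluorescence in situ hybridization (smRNA-FISH).
    Tiles a target transcript with candidate antisense 20-mers, enumerates
    on- and off-target hybridization sites across a transcriptome with a
    seed-and-extend local aligner, scores every duplex with a unified
    DNA/DNA nearest-neighbor thermodynamic model with sodium entropy
    correction, solves the coupled mass-action equilibrium of probe-target
    binding, probe self-hybridization and probe cross-dimerization, and
    summarises specificity through Poisson-Binomial bound-probe-count
    distributions, expression-weighted on/off-target molecule counts and a
    probe-set specificity load. Probes are assembled by a prioritization-rank
    greedy selection that prefers probes without off-targets and penalises
    cross-dimerization against probes already chosen. Includes a
    deterministic synthetic-fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    optparse,
    pracma,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
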