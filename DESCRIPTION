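Package: paleomito
Title: Ancestral-Node Divergence Dating for Low-Coverage Ancient
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for divergence dating of damage-prone,
    low-coverage ancient mitochondrial genomes. Simulates mitogenome
    evolution on dated trees under GTR+I+Gamma with post-mortem
    deamination damage, short-fragment libraries and PCR
    over-amplification; filters, dereplicates and greedily clusters reads
    at a fixed identity threshold; places reads with a minimal
    seed-and-extend mapper; calls end-trimmed majority consensus
    sequences with damage-misincorporation and windowed-depth profiles;
    assembles codon-position-partitioned supermatrices from annotated
    mitogenomes; computes partitioned pruning likelihoods, maximum
    likelihood branch lengths and marginal ancestral sequence
    reconstructions; performs Bayesian tip dating under an uncorrelated
    lognormal relaxed clock with a constant-size serial coalescent prior;
    and orchestrates read down-sampling and error-injection robustness
    experiments around the dating of reconstructed ancestral nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
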