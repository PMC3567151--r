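Package: decoysim
Title: Sexual Conflict Simulations with a Female Decoy Locus and
    Substitution-Rate Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based population simulations of sexual conflict over
    mating rate between a male-expressed ligand locus and a female-expressed
    receptor locus, extended with a female-expressed molecular decoy (a
    receptor mimic that binds ligand without effector function) and a neutral
    control locus.  Trajectories of mean allelic values are converted to
    windowed substitution rates and analysed with per-replicate linear
    regressions, correlation classification, replicate-level counts and
    Fisher's exact test; the same regression machinery applies to empirical
    branch-specific dN/dS tables from codon branch models.  The generation
    loop is implemented in C++ for speed and exact reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
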