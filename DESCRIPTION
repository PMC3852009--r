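Package: compsub
Title: Pathways of Compensatory Substitution in Finite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic rates and forward simulation for compensatory
    substitution at a pair of epistatically interacting loci. Two
    individually deleterious but jointly neutral mutations can fix either
    by way of a fixed deleterious intermediate (Type 1) or by a direct
    double substitution while both loci segregate (Type 2). The package
    provides diffusion-approximation fixation probabilities, the Wright
    stationary density of the pooled intermediate-haplotype frequency with
    Gauss-Jacobi quadrature, closed-form rates between the four fixed
    haplotype states, the embedded jump chain of fixed-state transitions,
    a Wright-Fisher forward simulator that classifies compensatory events
    by pathway, estimators for pathway probabilities and reversion counts,
    and a four-state phylogenetic substitution model with a pruning
    likelihood for paired-site data on a tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    ape,
    jsonlite,
    optparse,
    statmod,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
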