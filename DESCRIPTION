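Package: uephylo
Title: Exchangeable Site-Pattern Models, Flattening-Rank Quartet Inference,
    and Coalescent-Mixture Simulation on Rooted Species Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for symmetry-based phylogenomic models on site-pattern
    probability tensors. Implements the ultrametric-exchangeable (UE) model as
    a system of linear symmetry constraints on n-way state tensors, with model
    dimensions computed both by a structural recursion over the rooted tree and
    by numerical rank of the constraint system; the extended-exchangeable (EE)
    model obtained by acting on each tensor index with an invertible Markov
    matrix, together with its cofactor (adjugate) rooted-triple invariants and
    block-matrix rank conditions; SVD-score quartet inference from tensor
    flattenings with exact quartet amalgamation; and a mechanistic
    coalescent-mixture simulator (multispecies coalescent gene trees with
    GTR-type substitution) including closed-form spectral site-pattern
    distributions for small trees. Includes a strict Newick interface for
    rooted binary metric trees and a plain-text site-pattern count format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
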