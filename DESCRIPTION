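Package: pepqubo
Title: Coarse-Grained QUBO Design of Peptide Binders on Pocket Lattices
Version: 0.1.0
Authors@R:
    person("pepqubo", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physics-based de novo design of peptide binders by joint
    optimization of sequence and binding pose on a cubic pocket lattice.
    A Miyazawa-Jernigan derived pairwise contact potential with
    Lennard-Jones distance dependence is clustered into a reduced
    amino-acid alphabet, the design problem is encoded as a Quadratic
    Unconstrained Binary Optimization (QUBO) / Ising Hamiltonian over
    site, bond and ancilla binary variables, and low-energy states are
    found by exact enumeration or seeded simulated annealing. Decoded
    lattice chains are refined over the full 20-letter alphabet on the
    frozen geometry. Includes pose (fraction-of-native-contacts
    precision-recall) and sequence (reduced-alphabet position frequency)
    validation statistics and seeded synthetic pocket fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
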