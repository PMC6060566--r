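Package: ssosort
Title: Sorting Signed Linear and Circular Permutations by Super Short Operations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact polynomial-time sorting distances for signed and unsigned
    gene-order permutations under super short operations (1-reversals,
    2-reversals and 2-transpositions), including their cyclic variants and
    circular chromosomes.  Implements the displacement-vector / crossing-number
    calculus, the cyclic permutation graph with odd-component accounting, the
    candidate-set minimisation that yields the cyclic-SSO distance of a signed
    linear permutation, the reduction from circular chromosomes over all 2n
    linearizations, explicit minimum-length sorting sequences, the classical
    closed-form distances for the previously solved model variants, and a
    brute-force breadth-first-search oracle over the full state space for
    validation at small n.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
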