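Package: decyclemin
Title: Decycling-Set-Based Minimizer Orders for DNA k-mers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Low-density minimizer sketching of DNA sequences using k-mer
    orders built on Mykkeltveit minimum decycling sets (MDS). Provides an
    O(k) on-the-fly membership test for the MDS and its symmetric mirror,
    decycling- and double-decycling-partition minimizer orders that scale
    to arbitrarily large k without precomputing exponential-size sets,
    baseline orders (random XOR-hash, lexicographic, user-supplied k-mer
    set files, Miniception), windowed minimizer selection with the window
    guarantee, and a density-evaluation harness (expected and particular
    density factors, forward-scheme lower bound, i.i.d. sequence
    generation, parameter sweeps). Includes small-k explicit enumeration
    and de Bruijn graph verification oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
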