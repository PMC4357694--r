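Package: dcopt
Title: Degenerate Codon Library Design by Integer Dynamic Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs degenerate-codon libraries for directed evolution from
    per-position amino-acid count tables. Minimizes an integer error function
    (the summed counts of desired amino acids excluded by the chosen codons,
    optionally plus integer penalties for unwanted ones) subject to a limit on
    the number of DNA sequences the library defines, using an exact dynamic
    program over error levels. A second dynamic program allows several
    degenerate codons per position while budgeting the primers required to
    synthesize each contiguous stretch of the gene, and both report the Pareto
    front of library size against error. Includes IUPAC degenerate-codon
    algebra, coverage-class reduction of the 3375-codon universe, brute-force
    reference oracles, report tables, a seeded fixture generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
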