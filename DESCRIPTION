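Package: psrecon
Title: Reconstruction of Constant-Weight Binary Strings from Prefix-Suffix Compositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing multisets of same-length, same-weight
    binary strings from the multiset of compositions (zero count, one count)
    of all of their prefixes and suffixes, the readout model of polymer- and
    DNA-based data storage channels that sequence molecules from both ends.
    Provides the composition bookkeeping grids, cumulative weight functions
    with their component-function algebra (median weights, discrepancies,
    maximal intervals, swaps), a linear-time greedy solver producing one
    compatible multiset, a complete scan-and-assembly enumerator of all
    compatible multisets up to reversal, a criterion-based test for unique
    reconstructibility, a brute-force oracle for small instances, and
    plain-text file formats with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
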