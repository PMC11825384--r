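Package: shapedesign
Title: Shape-Aware Design of DNA Point Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates substitution candidates of a wild-type DNA sequence
    (up to seven mutable positions, the full 4^k Cartesian product) and scores
    each candidate along two axes of protein-DNA recognition: base readout,
    via a physicochemical functional-group encoding of the major and minor
    groove edges (with one-hot and Levenshtein alternatives), and shape
    readout, via Euclidean or Pearson distances over a catalogue of fourteen
    DNA shape features (six base-pair step, six intra-base-pair, minor groove
    width and electrostatic potential) predicted by a pluggable k-mer
    lookup-table backend. Includes a deterministic synthetic-table generator,
    focal-region restriction of shape distances, Pareto-front extraction over
    the (base distance, shape distance) plane, TSV/JSON output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
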