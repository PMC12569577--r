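Package: fcodetools
Title: Kinship Path Encoding, Family Files and Inbreeding Coefficients
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Fcode kinship-encoding notation, in which every
    member of a family is written as a path of relationship layers (parent,
    sibling, child, spouse, each with an optional birth-order number) rooted
    at a reference person, the origin of coordinates. Provides a validating
    parser and renderer, a term-rewriting normalizer that repairs the eight
    redundant path patterns, reading and writing of tab-separated FDATA and
    extended TSV family files, a kinship graph with relationship queries,
    substring/regex search and re-rooting to a new reference person,
    common-ancestor detection with a path-counting inbreeding coefficient,
    seeded random generation of valid codes and families, exporters to
    Graphviz DOT, HTML reports and LINKAGE/PED pedigree files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, igraph, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'constants.R'
    'AllClasses.R'
    'parse.R'
    'normalize.R'
    'family-io.R'
    'graph.R'
    'kinship.R'
    'synthgen.R'
    'export.R'
    'cli.R'
    'fcodetools-package.R'
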