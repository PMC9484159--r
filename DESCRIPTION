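Package: chemlike
Title: Analysis of Chemistry-Like Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether an abstract reaction network (a directed,
    integer-weighted hypergraph) admits a chemical interpretation. Provides
    exact-arithmetic tests for thermodynamic soundness (lax and strict, with
    energy witnesses or futile-cycle certificates), conservativity (positive
    conservation laws or cornucopia/abyss certificates), enumeration of
    support-minimal futile cycles and minimal moiety conservation laws,
    detection of obligatory isomers and oligomers, construction of sum-formula
    and Lewis (vertex-coloured multigraph) realizations, and generation of
    random conservative, thermodynamically sound networks. Includes a text
    reaction format, TSV matrix input and output, built-in example fixtures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
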