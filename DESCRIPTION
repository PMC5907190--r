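Package: eciopt
Title: Minimum-Damage Enzyme Combination Identification in Boolean
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Boolean (AND/OR) models of metabolic networks in which
    reactions are AND nodes over their substrate compounds and catalyzing
    enzymes, and compounds are OR nodes over their producing reactions.
    Given such a network and a set of target compounds to be stopped,
    the package finds the enzyme set whose inhibition stops every target
    while rendering the fewest non-target compounds non-producible
    ("damage"), a model of drug-target selection with minimal
    side-effects.  Producibility is defined as the least fixed point of
    the AND/OR system, so self-sustaining cycles are never counted as
    producible.  The optimization is formulated as a 0/1 integer linear
    program with complementary true/false variable pairs per node and an
    acyclic-support (level) extension, solved by an exact built-in
    branch-and-bound; an exhaustive-search oracle, a deterministic random
    network generator, a polynomial reduction from minimum edge cover
    (the problem's hardness source), and a command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
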