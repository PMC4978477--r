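Package: coalearn
Title: Coalgebraic Models of Associative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corecursive (coalgebraic) models of associative learning.
    Provides generic recursion-scheme combinators (unfold/anamorphism,
    fold/catamorphism, product pairing, exponential transpose), typed
    directed-graph association networks with co-occurrence ("halfway")
    and Rescorla-Wagner strength-update rules, elemental and configural
    trial encodings, species-typed learning constraints, rote-learning
    simulations to criterion, built-in worked-example fixtures, a seeded
    generator of two-list learning conditions, and TSV/JSON/DOT
    input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
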