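Package: deidlp
Title: Spatial De-Identification of Patient Locations by Linear Programming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Creates de-identified patient location datasets by stochastically
    relocating patients among small areas (postal or ZIP codes) so that the
    probability of re-identifying any individual from a disclosed location is
    provably bounded while the expected displacement in meters is minimized.
    Implements the classic population-weighted linear-programming formulation
    and a revised formulation that stays feasible when area populations are
    smaller than the patient count, together with great-circle distances and
    nearest-k sparsification, constraint-redundancy pruning, a solver-agnostic
    optimization contract, an independent re-identification risk audit,
    multinomial patient relocation, and a synthetic-city generator for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    geosphere,
    methods,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
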