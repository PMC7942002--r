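Package: dqmm
Title: Knowledge-Based Data Quality Assessment with Measurement Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formalizes data-quality measurement methods (MMs) for clinical
    datasets as portable five-part rules (tags, domain paths, optional
    constraint check, optional grouping, characterization), executes them
    against path-addressed nested records, derives them automatically from
    variable reference types and constraint schemas, composes them into
    multi-layered measures, and packages them into version-control friendly
    knowledge bases. Includes the three adapted harmonized data-quality
    framework (HDQF) measures RepresentationComplete, TaskComplete and
    TDConstraints with per-variable heatmap reporting, and a synthetic
    multi-site study fixture generator with ground-truth missingness and
    constraint-violation injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
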