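Package: fbratio
Title: Flux Balance Analysis with Flux-Ratio Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based metabolic modeling with flux-ratio constraints
    embedded directly as rows of the stoichiometric matrix, so that branch
    point selectivity (the split of a metabolite pool among competing
    enzymes) can be imposed, audited, and rewritten to emulate gene
    knockdown, knockout, and over-expression, all while the flux balance
    problem remains an ordinary linear program. Includes readers and writers
    for SBML Level 3 (fbc bounds) and a compact JSON model dialect, a
    two-stage (maximize growth, then minimize total flux) solver, specific
    proton flux scans tracing the clostridial acidogenesis-solventogenesis
    transition, a bundled core model of Clostridium acetobutylicum
    fermentation, and strain-design helpers that translate enzyme-level
    edits into flux-ratio arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
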