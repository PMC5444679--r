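Package: marxFBA
Title: Flux Balance Analysis of Kluyveromyces marxianus Central Metabolism
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of central carbon metabolism in the
    xylose-utilising yeast Kluyveromyces marxianus. Provides a curated
    56-reaction stoichiometric reconstruction (glycolysis, pentose phosphate
    pathway, TCA cycle, fermentative branches, beta-oxidation, lumped electron
    transport at P/O 2.5 and a biomass drain), a linear-programming flux
    balance engine with parsimonious tie-breaking, flux variability analysis
    and substrate-cycle detection, and a suite of cofactor-balance scenarios
    (glucose versus xylose, fructose-1,6-bisphosphatase/phosphofructokinase
    manipulation, oxidative-PPP cofactor swaps, closed ATP balance, anaerobic
    growth). Includes generators for small random models with an independent
    vertex-enumeration optimum used to validate the solver, a plain-text
    model exchange format, and GraphML/DOT export of flux maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
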