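Package: chelspec
Title: Equilibrium Speciation and Biodistribution Statistics for Gadolinium Chelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-component chemical equilibrium speciation for ranking
    gadolinium chelators under physiological conditions, and the statistics
    pipeline for radiotracer metabolic-balance studies. Provides a Newton
    mass-balance solver over cumulative formation constants, pH-conditional
    stability constants, dilution and transmetallation competition scans with
    release thresholds and chelator ranking, percent-recovered-dose accounting
    with Dixon's Q outlier screening, one-way ANOVA with Dunnett and Tukey
    multiple comparisons, excretion time courses, and synthetic generators for
    murine balance studies and small thermodynamic test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    jsonlite
Config/testthat/edition: 3
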