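Package: fitdecline
Title: Declining Adaptability in Microbial Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the rule of declining adaptability: the
    empirical observation that, in a common environment, low-fitness
    microbial genotypes gain fitness faster per generation than fitter
    ones.  The package standardizes heterogeneous fitness measurements
    into per-generation Malthusian log-deficits and excess log-gains
    relative to the fittest founder, fits log-log-linear and exponential
    adaptability regressions, and extrapolates fitness trajectories and
    plateaus from the fitted slope.  A genotype-class Wright-Fisher
    simulator of asexual adaptation under clonal interference implements
    four macroscopic-epistasis models (diminishing beneficial effects,
    declining beneficial rate, a finite-sites model, and Fisher's
    geometric model), and a synthetic-data generator emulates the study
    designs the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
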