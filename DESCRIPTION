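Package: dmconflict
Title: Diffusion Model of Conflict Tasks: Simulation, Fitting, and Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and estimation of the diffusion model of
    conflict (DMC) for two-choice conflict tasks. A controlled constant-drift
    diffusion process is superimposed with an automatic process whose mean
    follows a scaled gamma function, producing congruency effects and
    negative-going delta functions. The package provides Monte Carlo
    first-passage simulation of the model, quantile-binned chi-squared fitting
    by differential evolution with simulation-based predictions, trial- and
    block-level data cleaning rules for conflict-task datasets, delta-function
    analysis, and synthetic-data generators shaped like hierarchical (Navon)
    and composite-face designs for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
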