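Package: mycdeg
Title: Kinetic Modelling of Ubiquitin-Mediated c-Myc Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of c-Myc turnover through
    the two SCF E3 ubiquitin-ligase adaptors FBXW7 (phosphorylation-dependent,
    driven by pulsed Erk and GSK3beta signals) and Skp2 (phosphorylation-
    independent), plus their combination under an exclusive on-off switch.
    Provides correlation-based parameter sensitivity analysis (Pearson,
    Spearman rank, and partial rank correlation coefficients with t-tests),
    Monte-Carlo perturbation-ensemble robustness analysis, and random-search
    optimization of the switching schedule that minimizes accumulated
    ubiquitinated c-Myc.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
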