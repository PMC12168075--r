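Package: rnacleave
Title: Top-Down Mass Spectrometry of RNA Backbone Cleavage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact monoisotopic mass and fragment-ion modelling for chemically
    modified RNA (deaza- and N2-methylguanosine, inosine), enumeration of
    McLuckey a/b/c/d/w/x/y/z backbone fragments and base-loss variants in
    negative ion mode, isotope-pattern generation, synthetic collisionally
    activated dissociation (CAD) spectra with a known per-site cleavage
    propensity model, peak-list deisotoping and fragment assignment with
    internal recalibration, site-specific cleavage-yield statistics with a
    random-cleavage null and a guanosine-preference factor, fold-change
    correlation analysis between modified and reference RNAs, and
    alkaline-hydrolysis product enumeration with pseudo-first-order rate
    estimation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
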