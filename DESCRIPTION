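Package: evorepair
Title: Compensatory Adaptation Analysis for Serial-Transfer Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for experimental-evolution studies of
    compensatory ("evolutionary repair") adaptation in budding yeast under
    DNA replication stress. Estimates relative fitness from two-colour
    flow-cytometry competition assays, fits power-law adaptation
    trajectories, detects convergent evolution with a Poisson recurrence
    test and Benjamini-Hochberg correction, calls copy-number variants
    from windowed read depths with a binomial recurrence test, and derives
    growth and cell-cycle phenotypes from plate-reader and DNA-content
    data. A synthetic-data generator emulates every input (Wright-Fisher
    serial-transfer populations, competition count sheets, depth profiles,
    logistic growth curves, DNA-content mixtures) so the full pipeline is
    testable without sequencing data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
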