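Package: erptopo
Title: Topographic Permutation Statistics for Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-by-point topographic analysis of variance (TANOVA) for
    multichannel event-related potential (ERP) data, using the global
    dissimilarity index between scalp maps as test statistic and
    within-subject permutation as the null model. Includes global duration
    statistics (GDS) for duration-based multiple-comparison correction
    across time, global field power (GFP) normalization for amplitude-free
    topography contrasts, permutation and variance-partition effect sizes,
    a deterministic preprocessing chain (zero-phase Butterworth filtering,
    average reference, baseline correction, amplitude-threshold artifact
    rejection, condition averaging), and a seedable generator for cued
    repetition-probability experiments with injectable topographic effects
    and spatially correlated, temporally autocorrelated noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
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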