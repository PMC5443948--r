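Package: eggspace
Title: Phenotypic Partitioning of Egg Appearance Among Brood-Parasite Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether sympatric host species of a shared avian
    brood parasite partition egg-phenotype space among species, and whether
    parasitic host-races match their own host better than other local hosts.
    Provides avian visual-model photon catches and granularity (Fourier
    bandpass) egg-pattern metrics; data hygiene (one egg per clutch,
    Mahalanobis outlier screening, collinearity checks, arcsine-square-root
    transform); from-scratch linear discriminant classification with
    leave-one-out jack-knifing, Monte-Carlo sample splitting and multinomial
    logistic regression; chance-expected classification nulls from group
    sample sizes with Fisher's exact and ranked Welch tests; host-race
    mimicry differentials; and Pagel's lambda phylogenetic signal estimated
    over sets of candidate trees. A seeded synthetic egg-community generator
    exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    jsonlite,
    ape,
    pracma,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nnet,
    phytools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
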