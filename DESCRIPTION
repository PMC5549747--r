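Package: scalescape
Title: Monte Carlo Exploration of Nucleobase/Amino-Acid Affinity Scale Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches the space of 20-element amino-acid weight scales for
    scales that maximize the proteome-average complementarity between mRNA
    nucleobase-density profiles and the scale-weighted sequence profiles of
    their cognate proteins. Provides windowed sequence-profile computation
    with a cached fast path, a zero-temperature downhill Monte Carlo search
    with simulated-annealing perturbation amplitudes, codon-usage-derived
    reference scales, hierarchical clustering of suboptimal-scale ensembles
    into fitness-landscape summaries, randomization-based significance tests
    with Fisher combination, and a seeded synthetic-proteome generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
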