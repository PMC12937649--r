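Package: rrfmm
Title: Reduced-Rank Frequency-Modulated Moebius Models for Multichannel ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically guided decomposition of multichannel
    event-related potentials (ERPs). Each channel is modelled as a linear
    mixture of a small number of latent oscillatory sources generated by
    equivalent current dipoles, with Frequency-Modulated Moebius (FMM)
    phase dynamics shared across channels. A rank-one restriction on each
    source's spatial mixing block encodes the fixed-dipole-orientation
    hypothesis; an alternating profile-likelihood estimator fits both the
    free (elliptical) and fixed (reduced-rank) variants, and channel-wise
    R-squared summaries compare them. Includes a dipole forward simulator
    for generating synthetic multichannel ERPs, delimited-text I/O for ERP
    matrices and electrode montages, broom-style tidiers, ggplot2
    visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
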