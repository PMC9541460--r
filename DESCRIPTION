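Package: reefugia
Title: Thermal-Stress Refugia Analysis for Coral Reef Climate Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify and track thermal-stress refugia on coral
    reefs from daily gridded sea-surface temperature ensembles. Implements
    the Coral Reef Watch degree-heating-week (DHW) stack (recentred
    maximum-monthly-mean climatology, HotSpot anomalies, 84-day DHW
    accumulation, austral-year annual maxima), percentile-based refugia
    classification with multi-model agreement maps, tidal and wind
    mixing-energy fluxes with a spatial block-bootstrap group comparison,
    and refugia-loss trajectories expressed against global warming level.
    A synthetic downscaled-ensemble generator with a planted
    mixing-protection mechanism makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
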