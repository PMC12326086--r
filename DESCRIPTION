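Package: flocktrace
Title: Flight and Flocking Dynamics of Homing Pigeons over Heterogeneous Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing homing-pigeon flight and flocking
    behaviour over heterogeneous landscapes from biologger streams. Converts
    5 Hz GPS logs and 100 Hz z-axis accelerometry into per-second flap
    frequency, flight speed and flock-geometry metrics (robust centroid,
    absolute spread, group size, front-back and left-right position), assigns
    open/wooded/urban ground-cover categories from GeoJSON habitat polygons,
    subsamples for temporal autocorrelation, and selects habitat-conditioned
    linear mixed models by exhaustive AIC search with variance-inflation
    pruning and Cook's-distance refitting. Includes a seeded flock-flight
    simulator with known ground truth so every stage is verifiable by oracle
    equivalence and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    lme4,
    lmerTest,
    car,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    knitr,
    rmarkdown
Config/testthat/edition: 3
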