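Package: flapturb
Title: Flapping-Flight Kinematics and Behaviour in Atmospheric Turbulence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline from raw biologger streams to effect-size inference for
    flapping fliers in turbulent air. Detects individual wingbeats from 200 Hz
    tri-axial (heave) acceleration, derives a pressure-based turbulence proxy
    (interquartile range of within-segment barometric fluctuations), converts
    barometric pressure to altitude and climb rate, decomposes GPS tracks into
    airspeed and headwind component via the wind triangle, summarises 15 s
    flight segments, and fits penalized additive models with flight random
    intercepts to quantify partial effects of turbulence as a percentage of
    each response's observed range. A synthetic-flight generator with known
    ground truth (turbulence level, wind, per-beat kinematics) makes every
    stage testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
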