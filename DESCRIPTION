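Package: whalebrs
Title: Shore-Based Behavioral Response Analysis for Gray Whales Exposed to
    Seismic Survey and Vessel Sound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shore-based behavioral response studies of baleen
    whales exposed to anthropogenic underwater sound. Converts theodolite
    angular fixes from known-height coastal stations into geographic
    positions (with earth-curvature and atmospheric-refraction corrections),
    resamples whale tracks on a 90-second criterion, computes movement and
    respiration response variables over 10.5-minute bins, attaches acoustic
    (per-type 30-s and cumulative sound exposure levels) and vessel-geometry
    covariates, interpolates benthic prey biomass by inverse-distance
    weighting and depth-aware regression kriging, and fits weighted
    generalized-least-squares / mixed models with selectable within-track
    residual correlation and BIC stepwise covariate selection. Includes a
    full synthetic-data generator (state-switching correlated random walks,
    seismic line acquisition, parametric sound propagation, theodolite
    observation process) so the entire pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
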