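Package: jbsi
Title: Jitter-Based Detection and Quantification of Spike Synchrony
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and quantifies precise firing synchrony between two
    simultaneously recorded spike trains using virtual spike jitter. The
    observed coincidence count is compared against its exact analytical null
    distribution under uniform jitter of the reference train (a Poisson-
    binomial law computed from per-spike synchrony probabilities), yielding a
    Z-score, an exact or normal-approximation p-value, and the Jitter-Based
    Synchrony Index (JBSI), a normalized index in [-1, 1]. Also provides
    classical cross-correlogram-based comparison indices (ECI, CCC, their
    corrected forms, and the JSSI), a Poisson spike-train simulator with
    refractory period, controlled coincidence injection and sinusoidal rate
    co-modulation, and a jitter-span sweep procedure for estimating the
    temporal precision of neuronal firing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, StatisticalMethod
RoxygenNote: 7.3.3
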