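Package: mabquant
Title: Quantitative Characterization of Patient-Derived Anti-LGI1 Monoclonal Antibodies
Version: 0.1.0
Authors@R:
    person("Maintainer", "mabquant", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for live cell-based assays of
    patient-derived monoclonal antibodies against the neuronal protein LGI1.
    Implements robust (median/MAD) per-frame normalization of fluorescence
    time-lapse stacks and the sum-above-threshold internalization statistic
    with time-lapse and static threshold variants; pHrodo-positive cluster
    counting and per-ROI positivity calls; one-site hyperbola equilibrium
    binding fits (Kd, Bmax) by damped least squares; end-point titre calling
    on dilution series and LRR:EPTP domain-titre ratios; cross-competition
    percent-blocking normalization with cross-blocking group inference
    (including one-way blockers and non-blockers); and replacement/silent
    somatic-mutation counting in immunoglobulin V regions. A synthetic-data
    generator with known ground truth drives every stage, so the full
    pipeline runs and is testable without microscopy or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
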