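Package: lvmap
Title: Spatiotemporal Mapping of Time-Varying Left-Ventricular Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting inter-protocol bias in time-varying
    left-ventricular (LV) surface geometries. Paired LV point-set sequences
    from two acquisition protocols (for example 3D echocardiography and
    cardiac magnetic resonance) are temporally aligned per subject with a
    penalty-modified dynamic time warping of normalised volume traces, and a
    partial least squares (NIPALS) regression maps one protocol's
    spatiotemporal geometry onto the other's. Includes standardized 145-point
    LV surface modelling, cavity volume and mass quantification, AHA
    17-segment labelling, clinical index derivation (EDV, ESV, EF, LVM, GLS
    and volume/strain rate indices), method-agreement statistics
    (Bland-Altman, ICC, paired t-tests), and a synthetic paired-population
    generator with a known injected inter-protocol bias for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
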