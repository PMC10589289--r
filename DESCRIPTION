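Package: phycopam
Title: PAM Fluorometry and Bio-Optical Analysis of Macroalgal Photophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pulse-amplitude-modulated (PAM) chlorophyll
    fluorescence and in-vivo optical spectra of macroalgae. Fits the Webb
    (1974) saturating-exponential model to rapid light curves to estimate the
    photosynthetic efficiency (alpha), the maximum relative electron transport
    rate (rETRmax), the light saturation parameter (E_K) and the maximum
    quantum yield of photosystem II (Fv/Fm); decomposes whole-tissue
    absorbance spectra into fluorescent (LHC II + PS II) and non-fluorescent
    (LHC I + PS I) fractions via phycoerythrin-peak normalization to estimate
    the fraction of chlorophyll a bonded to PS II; quantifies chlorophyll-a
    emission spectra under blue and green excitation with an
    excitation-intensity adjustment; and provides one- and two-way ANOVA with
    Tukey HSD post-hoc tests for season and tissue-age comparisons. A
    synthetic-data generator with known ground truth makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
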