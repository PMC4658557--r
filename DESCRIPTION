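Package: vocalid
Title: Vocal Individuality Analysis for Penguin Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual identity information in animal
    vocalisations from a source-filter perspective, developed around the
    contact calls and ecstatic display songs of the African penguin
    (Spheniscus demersus). Provides acoustic feature extraction (fundamental
    frequency contour statistics, jitter, shimmer, harmonics-to-noise ratio,
    Burg LPC formant tracking, formant dispersion and vocal tract length
    estimation, amplitude modulation and syllable structure), the Potential
    of Individual Coding (PIC) statistic with small-sample correction,
    stepwise linear discriminant analysis with Wilks' lambda variable
    selection and leave-one-out cross-validation, and a seeded source-filter
    call synthesizer for generating labelled test colonies with ground-truth
    feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
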