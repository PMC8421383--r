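Package: ehquant
Title: Quantification of Endolymphatic Hydrops from MR and Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify endolymphatic hydrops (EH) of the inner ear.
    Implements the HYDROPS and HYDROPS-Mi2 image compositions from
    multi-contrast gadolinium-enhanced MR volumes, rule-based selection of
    representative cochlear and vestibular slices (including the lateral
    semicircular canal arc-visibility criterion), negative-pixel EH-ratio
    measurement within regions of interest, and area-ratio morphometry of
    labeled histology-style sections (cochlear scala media, saccule and
    utricle, semicircular-canal ducts, and canal herniation of the otolithic
    organs). A synthetic inner-ear phantom generator with known ground-truth
    endolymph fractions allows every stage of the pipeline to be validated
    without patient data, and a two-group comparison workflow (normality
    test, then Welch t-test or Mann-Whitney) reproduces the study-level
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti,
    png
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
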