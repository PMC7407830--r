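Package: ternci
Title: Ternary Combination-Index Analysis for Co-Culture Inflammation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for plate-based co-culture inflammation
    assays testing a three-extract herbal combination: control-anchored
    normalisation of mediator release and transepithelial electrical
    resistance (TEER), constrained four-parameter logistic
    concentration-response fitting with IC50/EC50 and asymptotic 95%
    confidence intervals, a ternary Chou-style combination index with
    equal-parts (one-third) dosing and term extraction for inactive
    components, interaction categorisation on the Chou scale, and one- or
    two-way ANOVA with Dunnett's multiple-comparisons test against the
    stimulated control. Includes a synthetic plate-data generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    grDevices
Config/testthat/edition: 3
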