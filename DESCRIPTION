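Package: afquantile
Title: Quantile-Based Allele-Frequency Thresholds for Variant Filtering and Flagging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes variable allele-frequency thresholds for Mendelian-disease
    variant prioritization from disease prevalence, mode of inheritance,
    penetrance, detectance and variant-database size, using the binomial
    sampling model of allele counts under Hardy-Weinberg equilibrium.
    Supports filtering candidate-variant lists against frequency-annotated
    variant databases (absence, static-cutoff and quantile-based approaches),
    flagging database-resident disease-causing variants whose observed
    frequency is improbably high under their proposed disease model,
    generation of threshold lookup tables over prevalence and database-size
    grids, and Monte-Carlo validation of the filtering approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
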