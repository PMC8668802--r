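Package: ddquant
Title: Droplet Digital PCR Quantification and Host-Population Infection Surveys
Version: 0.1.0
Authors@R: person("ddquant", "maintainers", email = "maintainers@ddquant.org", role = c("aut", "cre"))
Description: Poisson partition statistics for droplet digital PCR (ddPCR):
    droplet classification against a fluorescence threshold, absolute
    quantification with exact (Garwood) confidence intervals, well quality
    control, assay validation (replicate reproducibility, dynamic-range
    linearity, limit of detection, primer efficiency), and conversion of
    reaction concentrations to infection loads (target copies per nanogram of
    total DNA). Downstream survey tools compute prevalence with Wilson score
    intervals, aggregation (variance-to-mean) indices, and pooled regression
    models over multiply imputed covariates (predictive-mean-matching chained
    equations with Rubin's-rules pooling). Forward simulators generate
    droplet-level wells, dilution series, and host survey tables with known
    truth so every pipeline stage is testable without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
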