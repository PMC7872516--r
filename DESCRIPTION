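Package: lipidmed
Title: Lifestyle, Lipoprotein Lipidomics, and Coronary Heart Disease Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how combined healthy-lifestyle factors act on
    coronary heart disease risk through an NMR-style lipoprotein lipid profile in
    a nested case-control design. Provides healthy-lifestyle-factor scoring from
    raw questionnaire and anthropometry fields, rank-based inverse-normal
    preparation of metabolite panels with duplicate-QC summaries and principal
    components, covariate-adjusted association layers with false-discovery-rate
    control, parametric causal mediation for a continuous mediator and rare
    binary outcome with exposure-mediator interaction, four-way effect
    decomposition and delta-method uncertainty, conditional stepwise construction
    of weighted genetic instruments within gene windows, and a synthetic
    nested case-control generator with analytically known ground-truth effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
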