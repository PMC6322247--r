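Package: collapsr
Title: Collapsibility Weights and Standardization for Epidemiologic Effect Measures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying collapsibility of epidemiologic effect
    measures in the counterfactual (potential-outcome) framework.  Implements
    exact collapsibility weights for the causal risk difference and the four
    codings of the causal risk ratio, a feasibility-envelope diagnostic that
    demonstrates the non-collapsibility of the odds ratio, Newman's weights
    for measures of association, identification of the risk-ratio weights
    from observed stratified 2x2 tables under no unmeasured confounding
    (Miettinen's weights), the standardized risk ratio, transport of
    stratum-specific risk ratios to external target populations, and a
    latent-confounder simulation that demonstrates how erroneous weights can
    interact with unmeasured confounding.  Includes a seeded synthetic
    population generator and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
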