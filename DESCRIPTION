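Package: nestveg
Title: Measurement-Timing Bias in Nest-Site Vegetation Effects on Nest Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation tools for quantifying how the timing of nest-site
    vegetation measurement biases estimated effects of vegetation structure
    on daily nest survival. Provides stochastic Michaelis-Menten canopy
    growth curves, discrete-time Bernoulli nest-survival simulation with
    left-truncated observer encounter histories, a logistic-exposure
    daily-survival model (binomial GLM with an exposure-dependent link)
    fitted through a formula interface, and a scenario runner that compares
    four vegetation measurement protocols by Monte Carlo bias and AIC
    model-selection frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), yaml, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
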