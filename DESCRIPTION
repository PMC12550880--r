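Package: thermotraits
Title: Thermal and Resource Competition Traits of Phytoplankton from
    Growth-Rate Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers resource-competition and thermal-performance traits of
    phytoplankton populations from crossed temperature-by-resource growth
    experiments. Provides a synthetic-data generator emulating a
    19-population, three-resource (light, nitrogen, phosphorus), six-temperature
    factorial design; piecewise growth-rate estimation from fluorescence time
    series; Bayesian Monod fits with derived competitive traits (R*, affinity,
    net maximum growth rate); Bayesian double-exponential thermal performance
    curve fits with derived thermal limits (Topt, Tmax, Tmin, thermal breadth);
    posterior-bootstrap GAM shape classification of trait-gradient
    relationships; and cross-population trait-association analyses (PCA,
    ANOSIM, Welch ANOVA with Games-Howell post hoc, Kendall correlations, and
    a constrained-resampling null for correlations with Tmax).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    mgcv,
    vegan,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
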