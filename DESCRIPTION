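Package: salivamigr
Title: Predicting Chemical Migration into Saliva and Mouthing Exposure from
    Children's Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts migration of organic chemicals from children's-product
    materials (PVC, polypropylene, EVA, silicone, wood) into saliva during
    mouthing, and screens the resulting exposure for non-cancer health risk.
    Implements a mechanistic material-saliva migration model (short-term
    Fickian diffusion switching to a two-exponential partition-limited
    saturation regime) driven by QSPR-estimated diffusion and
    material-saliva partition coefficients, a regression-based alternative
    fitted by forward selection, harmonization and synthetic generation of
    migration-rate datasets, log-scale validation statistics with three
    cross-validation schemes, and conversion of migration rates into daily
    mouthing doses and hazard quotients for age-specific mouthing scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
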