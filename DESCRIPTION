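Package: cherryfarm
Title: Individual-Based Virtual-Farm Simulation of the European Cherry Fruit Fly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, individual-based ("virtual farm") simulator of the
    European cherry fruit fly (Rhagoletis cerasi) on spatially explicit sweet
    cherry farms, for site-specific integrated pest management (IPM) studies.
    Each female fly is an agent whose daily decisions (exploration,
    micro-migration, oviposition) are stochastic and conditioned on her age,
    the weather, and the state of the 10 x 10 m farm sector she occupies.
    The package provides calibrated demographic schedules (staggered spring
    emergence, truncated Gompertz senescence, age-dependent fecundity),
    host-plant phenology with cultivar-specific fruit suitability windows,
    Rebel-trap monitoring, pesticide and harvest interventions with
    carry-over accounting, a mark-recapture virtual experiment, synthetic
    farm and weather generators, and the validation statistics (Monte-Carlo
    chi-square goodness of fit, 3-sigma control charts with run rules,
    replicate homogeneity) used to compare simulations with field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
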