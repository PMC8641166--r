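Package: afcost
Title: Real-World Cost Modelling of Atrial Fibrillation Anticoagulation
    Therapies
Version: 0.1.0
Authors@R:
    person("afcost", "maintainers", email = "afcost@example.org",
           role = c("aut", "cre"))
Description: Patient-specific real-world cost model for comparing warfarin
    and direct oral anticoagulant (DOAC) therapy in atrial fibrillation.
    Combines a seeded synthetic registry generator (cohort, healthcare
    contact streams, road-network geography, partial travel-reimbursement
    records), cohort selection and diagnosis filtering, fastest-route
    network analysis, a rule-based travel-mode classifier with daily trip
    limits, cost equations for travel, time, drugs and healthcare fees
    (including the annual payment ceiling), and group-level cost reporting
    with normal-theory confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
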