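Package: ehrmonitor
Title: Practice-Level Monitoring of Coded Clinical Activity in Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for surveillance of coded clinical activity in
    primary-care electronic health records. Discovers high-volume clinical
    codes from a long-format event table, groups them using a CTV3-style
    parent-child terminology hierarchy (prefix, subtree, and keyword rules),
    computes per-practice monthly rates per 1000 registered patients,
    summarises them as medians and deciles across practices, measures
    year-on-year percentage change, and classifies service disruption and
    recovery. Includes a fully seeded synthetic-data generator (practices,
    terminologies, overdispersed seasonal monthly counts with injectable
    disruption profiles and index-date attrition) so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
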