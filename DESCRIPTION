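Package: washpriority
Title: Stakeholder Priority Weighting for School Sanitation Operation and
    Maintenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Participatory multi-criteria decision analysis for water,
    sanitation and hygiene (WASH) priority setting. Implements the Analytic
    Hierarchy Process (principal-eigenvector weights from pairwise comparison
    matrices, Saaty consistency screening, geometric-mean aggregation of
    individual judgments), SWING indicator weighting, hierarchical composition
    of domain and local weights into global indicator priorities, bootstrap
    confidence intervals for domain weights and Kruskal-Wallis comparison of
    stakeholder groups.  Ships a reference two-level hierarchy of 6 domains
    and 33 indicators for school sanitation operation and maintenance, and a
    synthetic-elicitation generator that produces stakeholder cohorts with
    known ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
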