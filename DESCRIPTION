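Package: mitanet
Title: Signed miRNA-Target Network Scoring for Pressure-Overload Heart Failure Models
Version: 0.1.0
Authors@R: person("Experimental", "Cardiology Informatics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline from small-RNA differential expression through
    signed bipartite miRNA-target network construction and node-strength
    scoring to qPCR validation and echocardiographic phenotyping, for rodent
    pressure-overload models of left-ventricular hypertrophy and systolic
    heart failure. Includes a synthetic-data generator with planted ground
    truth (negative-binomial counts, interaction tables in three database
    dialects, Ct tables, echo measurements) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
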