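Package: domainHotspots
Title: Cross-Species Protein Domain Mutation Hotspot Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps human and yeast point mutations with phenotypic
    annotations onto shared protein-domain coordinates, scores
    per-position mutation clustering with a binomial order-statistic
    significance score (the DS-Score), calls and de-redundifies domain
    hotspots, links hotspots across species, classifies the cross-species
    relatability of mutations, and tests disease-phenotype co-occurrence
    with right-sided Fisher exact tests.  A seeded synthetic-data
    generator with a ground-truth ledger lets the full pipeline be
    exercised and calibrated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
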