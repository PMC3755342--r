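Package: midgutclones
Title: Clonal Lineage Simulation and Compartment Statistics for the
    Drosophila Midgut
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the regionalized Drosophila midgut epithelium as an
    ordered atlas of subregions on a cylindrical cell lattice, simulates
    intestinal stem cell (ISC) clone induction and growth with
    Gillespie-scheduled divisions and boundary-aware daughter placement,
    scores boundary clones (boundary cells, crossed cells, eligibility
    rules) and tabulates per-boundary crossing statistics including the
    binomial all-fail null and expected-crossing chi-square tests,
    estimates per-region ISC division rates from clone-size time courses,
    and screens fpkm expression matrices for region- and zone-enriched
    genes under replicate quality-control rules. Ships a packaged
    clonal-analysis count table and synthetic generators so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
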