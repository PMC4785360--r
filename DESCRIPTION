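Package: dranet
Title: Drug-Response-Associated Gene Discovery with Differential Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes whose baseline expression is associated with drug
    sensitivity (activity area) across a cancer cell-line panel, using per-gene
    confounder-adjusted linear regression with Benjamini-Hochberg control and
    permutation nulls; clusters samples into sensitive and non-sensitive groups;
    tests top-k ranked-list overlap between sample strata; computes modular
    differential connectivity (MDC) between resistant and sensitive cell lines
    over gene-set modules with one-sided permutation FDR; and identifies key
    driver genes by hypergeometric enrichment of module genes in 2-hop
    protein-interaction neighborhoods. Includes a synthetic panel generator with
    planted associations, differentially connected modules, and network hubs for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
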