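Package: fluencynets
Title: Group-Based Semantic Network Analysis of Verbal Fluency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and compares group-level semantic memory networks from
    semantic verbal fluency responses. Responses are cleaned, binarized into a
    participant-by-word incidence matrix, equated across groups, converted to
    cosine similarities, sparsified with the Triangulated Maximally Filtered
    Graph (TMFG), and binarized into unweighted undirected graphs. The package
    computes small-world network measures (clustering coefficient, average
    shortest path length, Louvain modularity, Humphries-Gurney
    small-world-ness), validates them against Erdos-Renyi null ensembles with
    Z-tests, compares groups with graded bootstrap partial-network t-tests,
    and tests unique-response production with McNemar's chi-squared test.
    Also included: Alternative Uses Task scoring (fluency, flexibility,
    creativity, overall divergent thinking), median-split grouping, and a
    censored-random-walk generator of synthetic two-group fluency studies
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
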