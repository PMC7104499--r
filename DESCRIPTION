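Package: gtxpanel
Title: Marker-Gene Panel Discrimination of Genotoxic Hepatocarcinogens
    from Targeted Liver RNA-Seq
Version: 0.1.0
Authors@R:
    person("gtxpanel", "developers", email = "gtxpanel@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for a 12-gene rat liver marker panel that
    discriminates genotoxic hepatocarcinogens (GTHC) from non-genotoxic
    hepatocarcinogens and non-carcinogens (NGTHC/NGTNHC) using targeted
    RNA-Seq read counts. Implements reference-gene normalization to
    log2(exp/cont) ratios, per-gene Tukey HSD group comparisons backed by
    a numerically integrated studentized-range distribution, combined-panel
    principal component analysis with a PC1 decision border, and the
    portable fixed-coefficient approximate-PC1 (Y1) score with its
    published constants. A synthetic-data module generates negative
    binomial count tables and labeled reference ratio panels so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
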