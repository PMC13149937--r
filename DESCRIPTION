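Package: pleioscan
Title: Mapping Pleiotropic Genes Behind Genetic Correlations Across Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for mapping gene-level pleiotropy from multi-disease
    GWAS summary statistics. Estimates pairwise genetic correlations by
    cross-trait LD-score regression and extracts the fully connected disease
    cluster; identifies pleiotropic genes by three routes: gene-based
    association tests (SKAT-O and principal-component tests combined with the
    Cauchy combination), genome-wide significant coding SNPs shared across
    diseases, and subset-based cross-trait meta-analysis followed by
    PLINK-semantics clumping and locus merging. Results are integrated into a
    disease-gene network with local hypergeometric gene-set enrichment. A
    synthetic-data module simulates summary statistics over block-diagonal LD
    with planted causal genes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
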