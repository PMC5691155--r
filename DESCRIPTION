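Package: pathpgs
Title: Pathway-Partitioned Polygenic Risk Scores for Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical machinery for a case-control genome-wide association
    study of a common binary trait and for pathway-level pleiotropy analysis:
    a fast linear association screen with logistic refitting, inverse-variance
    fixed-effect meta-analysis and genomic-control diagnostics; distance-based
    locus definition with stepwise conditional selection of distinct SNPs and
    a replication filter; genetic relationship matrices, average-information
    REML variance components and the liability-scale transformation;
    joint re-estimation of SNP weights and locus-, pathway- and genome-level
    polygenic risk scores with trait-association scans under Storey q-value
    control; regional genotypic scores for cross-trait pleiotropy; and
    community detection on pathway co-membership graphs. Includes a
    synthetic-data generator (block-LD genotypes, liability-threshold
    phenotypes, pathway-restricted shared effects) so the whole pipeline is
    testable without access to biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
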