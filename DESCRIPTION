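Package: lipidgen
Title: Replication and Generalization of Lipid-Trait SNP Associations
    Across Diverse Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether GWAS-identified lipid variants
    replicate in European-descent samples and generalize to other
    populations.  Implements per-stratum additive-model association
    testing for HDL-C, LDL-C, and ln(TG), fixed-effects inverse-variance
    meta-analysis with Cochran's Q and I-squared heterogeneity,
    replication/generalization classification from summary statistics,
    analytic power and expected-versus-observed significance accounting,
    Weir-Cockerham F_ST and two-locus linkage-disequilibrium
    descriptives, and a seeded multi-population cohort simulator for
    end-to-end validation.  Ships published multi-population summary
    tables for 49 lipid SNPs as example data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
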