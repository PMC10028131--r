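Package: hccMRD
Title: Plasma-Only ctDNA Minimal Residual Disease Analysis for Resected
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tumor-agnostic (plasma-only) circulating tumor DNA analysis for
    minimal residual disease (MRD) detection after curative liver resection.
    Provides cohort mutational-landscape statistics (gene mutation
    frequencies, variant and base-substitution class spectra, pathway
    burden, co-occurrence/mutual-exclusivity testing, positional-clustering
    driver scores), construction of an MRD monitoring gene panel by
    frequency subtraction between a disease cohort and a long-term
    relapse-free control cohort, the one-or-more-panel-mutation MRD
    positivity rule, relapse-prediction evaluation (confusion metrics,
    Kaplan-Meier, log-rank, univariable Cox), longitudinal MRD trajectory
    tracking, a binomial low-VAF locus caller, and calibrated synthetic
    cohort generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
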