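Package: mitotwin
Title: Twin-Pair Analyses of Mitochondrial DNA Quantity, DNA Methylation
    and Obesity Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for twin-cohort studies linking adipose
    tissue DNA methylation, mitochondrial DNA quantity (mtDNAq) and
    obesity-related traits: qPCR relative quantification of mtDNA with
    calibrated normalized relative quantities (CNRQ) and stochastic
    regression imputation; a Gaussian generalized estimating equation
    (GEE) engine with exchangeable working correlation and sandwich
    covariance; a probe-wise epigenome-wide association scan (EWAS) with
    a consensus intra-pair correlation and empirical-Bayes moderated
    t-statistics; the ICE FALCON cross-twin cross-trait regression
    procedure with pair-bootstrap coefficient-change tests and causal
    pattern classification; batteries of standardized trait associations
    with FDR control and a marginal/conditional R-squared variance
    partition. A synthetic twin-cohort generator with configurable causal
    structure provides ground truth for parameter-recovery testing, so no
    restricted cohort data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
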