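Package: cacprog
Title: Genetic Risk Scores and the Progression of Coronary Artery Calcification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between polygenic risk scores
    and the progression of coronary artery calcification (CAC) in longitudinal
    cohorts with two CT scans. Implements weighted and unweighted allele-dosage
    risk scores with linkage-disequilibrium pruning and allele-frequency
    imputation of missing genotypes; two continuous progression endpoints (the
    deviation of observed from percentile-tracking expected log(CAC+1), and the
    5-year normalized log-progression); scan-pair quality-control flags; an
    age- and sex-conditional empirical percentile surface for baseline CAC; a
    covariate-adjusted association stack (ordinary, heteroscedasticity-robust
    and quantile regression, quartile contrasts, per-SNP scans) with
    percent-scale effect transformation, incremental explained variance and
    Bonferroni multiplicity control; and a synthetic cohort generator with
    known planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
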