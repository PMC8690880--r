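Package: tcellri
Title: Indirect Reference Intervals for T-Lymphocyte Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Establishes age- and sex-stratified reference intervals for
    T-lymphocyte subset measurements (CD3+, CD3+CD4+, CD3+CD8+ percentages and
    absolute counts) from laboratory-information-system style records using the
    indirect method: skewness/kurtosis normality assessment, Box-Cox
    normalization with maximum-likelihood lambda, Tukey-fence outlier
    elimination on the transformed scale, Harris-Boyd partition testing per
    CLSI EP28-A3C, and nonparametric 2.5th-97.5th percentile limits, together
    with external verification, age-trend statistics, and a synthetic cohort
    generator with closed-form interval oracles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
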