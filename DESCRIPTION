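Package: pedbpref
Title: Percentile-Based Pediatric Oscillometric Blood Pressure Reference Values
Version: 0.1.0
Authors@R:
    person("LOFUS", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Construction and benchmarking of percentile-based oscillometric
    office blood pressure reference values for children and adolescents.
    Provides a synthetic pediatric cohort generator with age-trending,
    heteroscedastic blood pressure; cohort preparation (triplicate-reading
    averaging, LMS-based BMI standard deviation scores, IOTF-style overweight
    classification, register-flag exclusions); linear, restricted cubic spline
    and quantile regression model fitting with non-crossing percentile table
    emission; percentile engines for lookup-table, Gaussian-polynomial and
    quantile-fit reference systems with guideline classification rules; and
    concordance analysis between reference systems (reclassification tables,
    detection and false negative/positive rates, 95th-percentile gaps,
    Bland-Altman limits of agreement). A command-line pipeline ties the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
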