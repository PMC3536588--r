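Package: xmricc
Title: XmR Control-Chart Scoring and Intraclass-Correlation Monitoring of
    Expenditure Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential XmR (individuals and moving-range) control-chart
    scoring of wide-format monthly expenditure tables into signed
    standard-deviation distances and ordinal band codes; year-level
    homogeneity assessment via the two-way ANOVA consistency average-measure
    intraclass correlation coefficient (equal to Cronbach's alpha) with
    F-based 95 percent confidence intervals, standard error of measurement,
    and separation/strata indices; yearly ICC trend statistics; Rasch
    rating-scale scenario simulation for calibration; and bubble-chart
    outlier flagging of consecutively out-of-control cases. Designed for
    monitoring cost containment across healthcare providers in single-payer
    reimbursement systems, but applicable to any cases-by-months monetary
    panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
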