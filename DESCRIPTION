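Package: hierwin
Title: Stratified Win Ratio Analysis for Hierarchical Composite Endpoints
    in Acute Heart Failure Trials
Version: 0.1.0
Authors@R:
    person("Trial", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the stratified win ratio (generalized pairwise
    comparison) analysis of a four-level hierarchical composite endpoint
    used in acute heart failure trials: time to all-cause death, number of
    heart failure events (HFEs), time to first HFE, and change from
    baseline in the Kansas City Cardiomyopathy Questionnaire Total Symptom
    Score (KCCQ-TSS) with a 5-point win margin.  Pairwise comparisons are
    censoring-aware (restricted to the common follow-up of each pair),
    strata are combined with Mantel-Haenszel-analogous weights, and
    inference uses the asymptotic normal two-sample U-statistic variance
    on the log win ratio.  Missing day-90 KCCQ-TSS is handled by multiple
    imputation stratified by on/off-treatment status with Rubin pooling.
    Also provides the bespoke secondary endpoints of such trials (loop
    diuretic dose standardization and diuretic response, days alive and
    out of hospital, trapezoidal AUC of change in log NT-proBNP, KCCQ
    responder status), a synthetic trial generator with known ground
    truth, a power/type-I-error simulation driver, and a command-line
    pipeline producing tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
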