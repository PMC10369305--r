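Package: oabandit
Title: Adaptive Allocation of Opioid-Risk Counseling with a LinUCB
    Contextual Bandit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop decision engine for adaptive opioid-analgesic (OA)
    risk reduction after emergency-department discharge. Computes a weekly
    patient-reported OA risk score from daily interactive voice response
    (IVR) monitoring items, allocates one of three counseling modalities
    (brief IVR, extended IVR, live counselor call) per patient-week with a
    LinUCB contextual bandit that conserves counselor time on ties, and
    pools learning across patients under rolling enrollment. Includes a
    synthetic cohort simulator calibrated to published engagement and
    baseline marginals, a trial engine with replayable audit logs, and the
    evaluation analyses: a multinomial logit of the decision mix with
    patient-clustered sandwich errors and mixed-effects quasi-Poisson
    models of risk-score trends with baseline-risk-stratum interactions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    nlme,
    nnet,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
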