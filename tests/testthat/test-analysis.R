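# Decision-mix multinomial logit and risk-trend quasi-Poisson models.

test_that("multinomial log-likelihood matches an optimizer oracle", {
  set.seed(80)
  n <- 20L
  fix <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:5), each = 4),
    calendar_week = sample(1:40, n, replace = TRUE),
    session_number = sample(1:12, n, replace = TRUE),
    chosen_arm = sample(arm_levels(), n, replace = TRUE))
  m <- fit_decision_mix(fix)
  X <- cbind(1, fix$calendar_week, fix$session_number)
  y <- as.integer(factor(fix$chosen_arm, levels = arm_levels()))
  oracle <- oracle_multinom_ml(X, y, K = 3L)
  expect_equal(m$logLik, oracle$logLik, tolerance = 1e-6)
})

test_that("clustered SEs exceed naive SEs under within-patient correlation", {
  set.seed(81)
  # strong patient-level utility shifts induce positive correlation
  recs <- sim_decision_panel(120L, beta_ext = c(0, 0, 0),
                             beta_csl = c(0, 0, 0), cluster_sd = 1.5)
  m <- fit_decision_mix(recs)
  naive <- matrix(sqrt(diag(vcov(m$fit))), nrow = 2, byrow = TRUE)
  # intercept columns carry the cluster effect; compare intercept SEs
  expect_gt(m$se[1, 1], naive[1, 1])
  expect_gt(m$se[2, 1], naive[2, 1])
})

test_that("degenerate decision logs raise a diagnostic error", {
  one_arm <- data.frame(patient_id = "P1", calendar_week = 1:20,
                        session_number = rep(1:10, 2),
                        chosen_arm = "brief_ivr")
  expect_error(fit_decision_mix(one_arm), "degenerate")
  expect_error(fit_decision_mix(data.frame(chosen_arm = "x")), "columns")
})

test_that("predicted session-type mixes are coherent probabilities", {
  skel <- structure(list(
    coef = matrix(0, 2, 3,
                  dimnames = list(c("extended_ivr", "counselor"),
                                  c("(Intercept)", "enrollment_week",
                                    "session_number"))),
    levels = arm_levels()), class = "decision_mix")
  p <- predict_decision_mix(skel, weeks = c(1, 60, 130), session = 1)
  expect_equal(unname(as.matrix(p[, -1])),
               matrix(1 / 3, 3, 3), tolerance = 1e-12)

  skel$coef["counselor", "enrollment_week"] <- -0.02
  p <- predict_decision_mix(skel, weeks = 1:130, session = 1)
  expect_true(all(diff(p$counselor) < 0))
  expect_equal(rowSums(as.matrix(p[, -1])), rep(1, 130))
})

test_that("fixed-effects quasi-Poisson reduction matches an IRLS oracle", {
  set.seed(82)
  sim <- sim_score_panel(60L)
  m <- fit_risk_trend(sim$scores, sim$baselines, "stratified",
                      random_intercept = FALSE)
  d <- merge(sim$scores, sim$baselines)
  d <- data.frame(value = d$value, enrollment_week = d$calendar_week,
                  session = d$session_number, stratum = d$comm_stratum)
  X <- model.matrix(~ enrollment_week + session + stratum +
                      enrollment_week:stratum, d)
  beta <- setNames(oracle_poisson_irls(X, d$value), colnames(X))
  got <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_equal(got[names(beta)], beta, tolerance = 1e-6)
})

test_that("constant scores yield null slopes, and nesting lifts fit", {
  flat <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 8),
                     calendar_week = rep(1:8, 10) + rep(0:9, each = 8),
                     session_number = rep(1:8, 10),
                     value = 1)
  m <- fit_risk_trend(flat, random_intercept = FALSE)
  slopes <- m$coefficients$estimate[m$coefficients$term != "(Intercept)"]
  expect_lt(max(abs(slopes)), 1e-8)

  set.seed(83)
  sim <- sim_score_panel(150L, b_s3 = 1, b_s3w = -0.006)
  base <- fit_risk_trend(sim$scores, sim$baselines, "base")
  strat <- fit_risk_trend(sim$scores, sim$baselines, "stratified")
  expect_gt(strat$quasi_loglik, base$quasi_loglik)
  expect_gt(strat$sigma_patient, 0)
  expect_error(fit_risk_trend(sim$scores[1:3, ], sim$baselines),
               "at least 2 patients")
})

test_that("predicted trajectories follow the fitted coefficients", {
  skel <- structure(list(
    coefficients = data.frame(
      term = c("(Intercept)", "enrollment_week", "session",
               "stratum2-5", "stratum>=6",
               "enrollment_week:stratum2-5",
               "enrollment_week:stratum>=6"),
      estimate = c(0, 0, 0, 0.2, 0.7, 0, -0.004)),
    session_mean = 6), class = "risk_trend")
  tr <- predict_risk_trajectories(skel, weeks = 1:120)
  expect_true(all(tr$predicted > 0))
  flat <- tr$predicted[tr$stratum == "1"]
  expect_equal(flat, rep(1, 120))                 # intercept-only stratum
  hi <- tr$predicted[tr$stratum == ">=6"]
  expect_true(all(diff(hi) < 0))                  # negative interaction
  expect_equal(hi[1], exp(0.7 - 0.004), tolerance = 1e-12)
  lo <- tr$predicted[tr$stratum == "2-5"]
  expect_true(all(lo < hi[1] & lo > flat[1]))     # ordered by main effect
})

test_that("trend models fitted on engine output recover direction", {
  run <- run_trial(small_config(n_patients = 40L, span = 30L), seed = 84)
  m <- fit_risk_trend(run$scores, run$cohort, "base")
  # within-patient improvement: treatment lowers risk across sessions
  sess <- m$coefficients[m$coefficients$term == "session", ]
  expect_lt(sess$estimate, 0)
  mix <- fit_decision_mix(run$decisions)
  expect_identical(mix$n_decisions, nrow(run$decisions))
  expect_true(all(is.finite(unlist(mix$se))))
})
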