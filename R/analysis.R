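# Evaluation analyses applied to decision logs.
#
# 1. Decision-mix trend: multinomial logit of the 3-level session type on
#    enrollment week (1-130) and ordinal session number (1-12), with
#    sandwich standard errors clustered on patient (weekly decisions are
#    correlated within patients). Brief IVR is the reference category.
# 2. Risk-score trend: log-link models of the weekly OA risk score with a
#    Poisson variance function. The outcome is a weekly item average, so
#    it is non-integer: quasi-likelihood is used, with a patient random
#    intercept (penalized quasi-likelihood fit). The "stratified" spec
#    adds baseline COMM-stratum main effects and stratum-by-week
#    interactions; fitting is complete-case over scored patient-weeks.

#' Fit the decision-mix trend model
#'
#' Maximum-likelihood multinomial logit of the chosen session type
#' (reference: brief IVR) on enrollment week and session number, with
#' patient-clustered sandwich standard errors. The sandwich meat is built
#' from the analytic multinomial scores \eqn{(1[y_i=k]-p_{ik})x_i} summed
#' within patients, with a G/(G-1) small-sample factor; the bread is the
#' inverse observed information of the ML fit.
#'
#' @param records Decision log: data frame with `chosen_arm`,
#'   `calendar_week` (enrollment week of the decision), `session_number`
#'   and `patient_id` (the cluster variable), e.g. `run$decisions` from
#'   [run_trial()].
#' @return Object of class `decision_mix`: per-contrast coefficient matrix
#'   (`coef`, rows = non-reference arms, columns = intercept/week/session),
#'   clustered `se`, `z`, `p`, full clustered `vcov`, `logLik`,
#'   `n_decisions`, `n_patients`, and the underlying `nnet::multinom` fit.
#' @export
fit_decision_mix <- function(records) {
  need <- c("chosen_arm", "calendar_week", "session_number", "patient_id")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("decision records are missing columns: ",
         paste(miss, collapse = ", "))
  d <- data.frame(
    arm = factor(records$chosen_arm, levels = arm_levels()),
    enrollment_week = as.numeric(records$calendar_week),
    session_number = as.numeric(records$session_number),
    patient_id = as.character(records$patient_id))
  d$arm <- droplevels(d$arm)
  if (nlevels(d$arm) < 2L)
    stop("degenerate decision log: fewer than 2 session types present (",
         paste(levels(d$arm), collapse = ", "),
         "); the decision-mix model is not identified")
  fit <- nnet::multinom(arm ~ enrollment_week + session_number, data = d,
                        trace = FALSE, Hess = TRUE, maxit = 1000)
  if (fit$convergence != 0)
    stop("multinomial logit did not converge (nnet code ",
         fit$convergence, ")")
  cf <- coef(fit)
  if (is.null(dim(cf)))   # two-level outcome: promote to matrix
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(levels(d$arm)[2L], names(cf)))

  # clustered sandwich: bread = vcov (inverse observed information)
  X <- model.matrix(~ enrollment_week + session_number, d)
  P <- fitted(fit)
  if (is.null(dim(P))) P <- cbind(1 - P, P)   # two-level case
  Y <- outer(as.integer(d$arm), seq_len(nlevels(d$arm)), "==") * 1
  K <- nlevels(d$arm); p <- ncol(X)
  scores <- matrix(0, nrow(d), (K - 1L) * p)
  cn <- character((K - 1L) * p)
  for (k in 2:K) {
    idx <- (k - 2L) * p + seq_len(p)
    scores[, idx] <- (Y[, k] - P[, k]) * X
    cn[idx] <- paste(levels(d$arm)[k], colnames(X), sep = ":")
  }
  colnames(scores) <- cn
  bread <- vcov(fit)
  # align score columns with the vcov ordering
  ord <- match(colnames(bread), cn)
  if (anyNA(ord)) ord <- seq_along(cn)   # fall back to construction order
  scores <- scores[, ord, drop = FALSE]
  cl <- rowsum(scores, d$patient_id)
  G <- nrow(cl)
  meat <- crossprod(cl) * G / (G - 1)
  V <- bread %*% meat %*% bread
  se_flat <- sqrt(diag(V))

  se <- matrix(se_flat, nrow = K - 1L, byrow = TRUE,
               dimnames = dimnames(cf))
  z <- cf / se
  structure(list(coef = cf, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), vcov = V,
                 logLik = as.numeric(logLik(fit)),
                 n_decisions = nrow(d),
                 n_patients = length(unique(d$patient_id)),
                 levels = levels(d$arm), fit = fit),
            class = "decision_mix")
}

#' @export
print.decision_mix <- function(x, ...) {
  cat("Decision-mix multinomial logit (reference: ", x$levels[1L],
      "), n = ", x$n_decisions, " decisions / ", x$n_patients,
      " patients\n", sep = "")
  for (k in rownames(x$coef)) {
    cat("\n", k, " vs ", x$levels[1L], ":\n", sep = "")
    print(round(rbind(coef = x$coef[k, ], se_cluster = x$se[k, ],
                      p = x$p[k, ]), 4))
  }
  invisible(x)
}

#' Predicted session-type probabilities over enrollment weeks
#'
#' Softmax of the fitted linear predictors at a fixed session number; the
#' model-based analogue of the decision-distribution-over-time figure.
#'
#' @param model A [fit_decision_mix()] result (any object with a `coef`
#'   matrix whose columns are intercept, enrollment week, session number,
#'   and a `levels` field naming the arms, reference first).
#' @param weeks Integer vector of enrollment weeks.
#' @param session Session number at which to evaluate (scalar).
#' @return Data frame with `enrollment_week` and one probability column
#'   per arm; rows sum to 1.
#' @export
predict_decision_mix <- function(model, weeks, session) {
  cf <- model$coef
  lv <- model$levels %||% c("ref", rownames(cf))
  lp <- matrix(0, length(weeks), nrow(cf) + 1L)
  for (k in seq_len(nrow(cf)))
    lp[, k + 1L] <- cf[k, 1L] + cf[k, 2L] * weeks + cf[k, 3L] * session
  pr <- exp(lp - apply(lp, 1L, max))
  pr <- pr / rowSums(pr)
  colnames(pr) <- lv
  cbind(data.frame(enrollment_week = weeks), as.data.frame(pr))
}

# Poisson quasi-log-likelihood; valid for non-integer outcomes, with the
# y = 0 limit of y*log(mu) taken as 0
quasi_poisson_loglik <- function(y, mu) {
  term <- ifelse(y > 0, y * log(mu), 0)
  sum(term - mu - lgamma(y + 1))
}

#' Fit the weekly risk-score trend model
#'
#' Log-link regression of the weekly OA risk score with a Poisson variance
#' function (the score distribution is right-skewed with a hard floor at
#' 1, and weekly item averages are non-integer, so quasi-likelihood is
#' used), a patient random intercept, and fixed effects for enrollment
#' week and session number. `model_spec = "stratified"` adds baseline
#' COMM-stratum main effects (2-5 and >=6 vs 1) and stratum-by-week
#' interactions. Fitting is restricted to patient-weeks with an observed
#' score. Set `random_intercept = FALSE` for the fixed-effects-only
#' quasi-Poisson GLM reduction.
#'
#' @param scores Weekly risk scores: data frame with `patient_id`,
#'   `calendar_week`, `session_number`, `value` (e.g. `run$scores`).
#' @param baselines Baseline records with `patient_id` and either
#'   `comm_stratum` or `comm_score`; only needed for the stratified spec.
#' @param model_spec `"base"` or `"stratified"`.
#' @param random_intercept Include the patient random intercept (default
#'   TRUE, via penalized quasi-likelihood).
#' @return Object of class `risk_trend`: `coefficients` table (estimate,
#'   se, statistic, p, 95% CI), `sigma_patient` (random-intercept SD, NA
#'   for the GLM reduction), `quasi_loglik` (Poisson quasi-log-likelihood
#'   at the population-level fitted means, for comparing nested
#'   fixed-effect specs), `session_mean`,
#'   `n_obs`, `n_patients`, `model_spec`, and the underlying fit.
#' @export
fit_risk_trend <- function(scores, baselines = NULL,
                           model_spec = c("base", "stratified"),
                           random_intercept = TRUE) {
  model_spec <- match.arg(model_spec)
  need <- c("patient_id", "calendar_week", "session_number", "value")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop("weekly scores are missing columns: ", paste(miss, collapse = ", "))
  d <- data.frame(patient_id = as.character(scores$patient_id),
                  enrollment_week = as.numeric(scores$calendar_week),
                  session = as.numeric(scores$session_number),
                  value = as.numeric(scores$value))
  d <- d[!is.na(d$value), , drop = FALSE]
  if (model_spec == "stratified") {
    if (is.null(baselines))
      stop("the stratified spec needs baseline records")
    b <- baselines
    if (!"comm_stratum" %in% names(b))
      b$comm_stratum <- comm_stratum(b$comm_score)
    d$stratum <- factor(
      as.character(b$comm_stratum[match(d$patient_id, b$patient_id)]),
      levels = c("1", "2-5", ">=6"))   # keep "1" the reference after CSV
    if (anyNA(d$stratum))
      stop("some patients in the scores have no baseline stratum")
  }
  tab <- table(d$patient_id)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 patients with at least 2 scored weeks")

  fixed <- if (model_spec == "base")
    value ~ enrollment_week + session
  else
    value ~ enrollment_week + session + stratum + enrollment_week:stratum

  if (random_intercept) {
    fit <- tryCatch(
      suppressMessages(MASS::glmmPQL(
        fixed, random = ~ 1 | patient_id,
        family = quasipoisson(link = "log"), data = d, verbose = FALSE)),
      error = function(e)
        stop("risk-trend model failed to converge: ",
             conditionMessage(e)))
    tt <- summary(fit)$tTable
    est <- tt[, "Value"]; se <- tt[, "Std.Error"]
    stat <- tt[, "t-value"]; pval <- tt[, "p-value"]
    sigma_patient <- suppressWarnings(
      as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]))
    # population-level fit: comparing nested fixed-effect structures via
    # conditional fits is confounded by the random intercepts, which absorb
    # between-patient effects; lme fitted values are link-scale
    mu <- exp(fitted(fit, level = 0))
  } else {
    fit <- glm(fixed, family = quasipoisson(link = "log"), data = d)
    if (!fit$converged)
      stop("risk-trend model failed to converge (IRLS)")
    sm <- summary(fit)$coefficients
    est <- sm[, 1L]; se <- sm[, 2L]; stat <- sm[, 3L]; pval <- sm[, 4L]
    sigma_patient <- NA_real_
    mu <- fitted(fit)
  }
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), statistic = unname(stat),
                      p = unname(pval),
                      ci_lo = unname(est - qnorm(0.975) * se),
                      ci_hi = unname(est + qnorm(0.975) * se),
                      row.names = NULL)
  structure(list(coefficients = coefs, sigma_patient = sigma_patient,
                 quasi_loglik = quasi_poisson_loglik(d$value, mu),
                 session_mean = mean(d$session),
                 n_obs = nrow(d),
                 n_patients = length(unique(d$patient_id)),
                 model_spec = model_spec,
                 random_intercept = random_intercept, fit = fit),
            class = "risk_trend")
}

#' @export
print.risk_trend <- function(x, ...) {
  cat("Risk-score trend (quasi-Poisson, ", x$model_spec,
      if (x$random_intercept) ", patient random intercept" else
        ", fixed effects only",
      "), n = ", x$n_obs, " patient-weeks / ", x$n_patients,
      " patients\n", sep = "")
  print(cbind(x$coefficients[1L],
              round(x$coefficients[-1L], 4)), row.names = FALSE)
  if (!is.na(x$sigma_patient))
    cat("patient random-intercept SD:", round(x$sigma_patient, 3), "\n")
  invisible(x)
}

# named-coefficient lookup, absent terms contribute 0
coef_lookup <- function(coefs, term) {
  i <- match(term, coefs$term)
  if (is.na(i)) 0 else coefs$estimate[i]
}

#' Predicted mean risk trajectories by baseline stratum
#'
#' Population-level predictions \eqn{\exp(\hat\eta)} over enrollment
#' weeks, with the session number fixed at its sample mean; the
#' model-based analogue of the predicted risk-trajectory figure.
#'
#' @param model A [fit_risk_trend()] result (stratified spec for per-
#'   stratum curves; with a base-spec model all strata share one curve).
#' @param weeks Integer vector of enrollment weeks.
#' @param strata Character vector of stratum labels (default all three).
#' @return Data frame with `stratum`, `enrollment_week`, `predicted`
#'   (mean risk score, always positive).
#' @export
predict_risk_trajectories <- function(model, weeks,
                                      strata = c("1", "2-5", ">=6")) {
  cf <- model$coefficients
  session <- model$session_mean %||% 0
  out <- expand.grid(stratum = strata, enrollment_week = weeks,
                     stringsAsFactors = FALSE)
  lp <- coef_lookup(cf, "(Intercept)") +
    coef_lookup(cf, "enrollment_week") * out$enrollment_week +
    coef_lookup(cf, "session") * session
  for (s in setdiff(unique(out$stratum), "1")) {
    hit <- out$stratum == s
    lp[hit] <- lp[hit] + coef_lookup(cf, paste0("stratum", s)) +
      coef_lookup(cf, paste0("enrollment_week:stratum", s)) *
        out$enrollment_week[hit]
  }
  out$predicted <- exp(lp)
  out[order(out$stratum, out$enrollment_week), , drop = FALSE]
}
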