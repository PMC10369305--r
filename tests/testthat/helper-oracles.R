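# Independent oracles and fixture builders shared across the test files.
# Every oracle here recomputes its quantity from first principles, without
# calling the implementation path it checks.

# ---- daily IVR fixture builders ------------------------------------------

# one patient-day row in the long daily IVR format
ivr_day <- function(patient_id = "P1", calendar_week = 1L, day_index = 1L,
                    completed = TRUE, pain_nrs = NA_real_,
                    oa_use_24h = NA, need = NA_integer_,
                    friend = NA_integer_, symptoms = NA_integer_,
                    pain_interference = NA_real_) {
  data.frame(patient_id = patient_id, calendar_week = calendar_week,
             day_index = day_index, completed = completed,
             pain_nrs = pain_nrs, oa_use_24h = oa_use_24h, need = need,
             friend = friend, symptoms = symptoms,
             pain_interference = pain_interference,
             stringsAsFactors = FALSE)
}

# a completed no-use day (risk items not asked)
nouse_day <- function(day_index, pain_nrs = 5, ...) {
  ivr_day(day_index = day_index, oa_use_24h = FALSE, pain_nrs = pain_nrs,
          ...)
}

# a completed use day with the three misuse items
use_day <- function(day_index, need, friend, symptoms, pain_nrs = 5, ...) {
  ivr_day(day_index = day_index, oa_use_24h = TRUE, pain_nrs = pain_nrs,
          need = need, friend = friend, symptoms = symptoms, ...)
}

# a random patient-week of daily rows (mixture of missed, no-use and use
# days), for property tests
random_week <- function(n_days = 5L, patient_id = "P1") {
  rows <- lapply(seq_len(n_days), function(i) {
    kind <- sample(c("missed", "nouse", "use"), 1L,
                   prob = c(0.4, 0.35, 0.25))
    switch(kind,
      missed = ivr_day(patient_id, day_index = i, completed = FALSE),
      nouse = nouse_day(i, patient_id = patient_id),
      use = use_day(i, sample(1:3, 1), sample(1:3, 1), sample(1:3, 1),
                    patient_id = patient_id))
  })
  do.call(rbind, rows)
}

# brute-force weekly risk score: re-derives completed days, use flags and
# per-item means with plain loops, then applies the printed formula
oracle_risk_score <- function(week) {
  completed_rows <- list()
  for (i in seq_len(nrow(week)))
    if (isTRUE(week$completed[i])) completed_rows <- c(completed_rows, i)
  if (!length(completed_rows)) return(NULL)
  any_use <- FALSE
  for (i in unlist(completed_rows))
    if (isTRUE(week$oa_use_24h[i])) any_use <- TRUE
  if (!any_use) return(1)
  total <- 0
  for (item in c("need", "friend", "symptoms")) {
    vals <- c()
    for (i in unlist(completed_rows))
      if (isTRUE(week$oa_use_24h[i]) && !is.na(week[[item]][i]))
        vals <- c(vals, week[[item]][i])
    avg <- if (length(vals)) sum(vals) / length(vals) else 3
    total <- total + (avg - 1)
  }
  7 - total
}

# ---- linear-model oracles ------------------------------------------------

# ridge regression with unit penalty: the closed form LinUCB's per-arm
# estimate must reproduce
oracle_ridge <- function(X, y) {
  solve(diag(ncol(X)) + crossprod(X), crossprod(X, y))
}

# multinomial-logit negative log-likelihood (reference category first);
# beta is a (K-1) x p matrix flattened row-wise
oracle_multinom_nll <- function(beta_flat, X, y, K) {
  p <- ncol(X)
  beta <- matrix(beta_flat, nrow = K - 1L, byrow = TRUE)
  eta <- cbind(0, X %*% t(beta))
  ll <- sum(eta[cbind(seq_along(y), y)] - log(rowSums(exp(eta))))
  -ll
}

# maximized multinomial log-likelihood via a general-purpose optimizer
oracle_multinom_ml <- function(X, y, K) {
  fit <- optim(rep(0, (K - 1L) * ncol(X)), oracle_multinom_nll,
               X = X, y = y, K = K, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(logLik = -fit$value, beta = fit$par)
}

# Poisson IRLS from scratch (log link); returns coefficients
oracle_poisson_irls <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 1e-8)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# ---- generative samplers for parameter-recovery studies ------------------

# decisions from a known multinomial logit over (enrollment week, session),
# with a patient-level random shift on each non-reference utility to induce
# within-patient correlation
sim_decision_panel <- function(n_patients, beta_ext, beta_csl,
                               span = 130L, sessions = 12L,
                               cluster_sd = 0.3) {
  entry <- sample.int(span, n_patients, replace = TRUE)
  u_ext <- rnorm(n_patients, 0, cluster_sd)
  u_csl <- rnorm(n_patients, 0, cluster_sd)
  rows <- vector("list", n_patients * sessions)
  k <- 0L
  for (i in seq_len(n_patients)) {
    for (s in seq_len(sessions)) {
      w <- entry[i] + s - 1L
      x <- c(1, w, s)
      eta <- c(0, sum(beta_ext * x) + u_ext[i], sum(beta_csl * x) + u_csl[i])
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = sprintf("P%04d", i), calendar_week = w,
        session_number = s,
        chosen_arm = sample(arm_levels(), 1L, prob = pr),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# weekly scores from a known log-link Poisson model with patient random
# intercepts and COMM-stratum-by-week interactions
sim_score_panel <- function(n_patients, b0 = 0.2, b_week = 0,
                            b_session = -0.01,
                            b_s2 = 0.22, b_s3 = 0.73,
                            b_s2w = -0.0014, b_s3w = -0.0041,
                            span = 130L, sessions = 12L, re_sd = 0.3) {
  entry <- sample.int(span, n_patients, replace = TRUE)
  stratum <- sample(c("1", "2-5", ">=6"), n_patients, replace = TRUE,
                    prob = c(65, 115, 48) / 228)
  u <- rnorm(n_patients, 0, re_sd)
  n <- n_patients * sessions
  i <- rep(seq_len(n_patients), each = sessions)
  s <- rep(seq_len(sessions), n_patients)
  w <- entry[i] + s - 1L
  lp <- b0 + b_week * w + b_session * s + u[i] +
    (stratum[i] == "2-5") * (b_s2 + b_s2w * w) +
    (stratum[i] == ">=6") * (b_s3 + b_s3w * w)
  list(scores = data.frame(patient_id = sprintf("P%04d", i),
                           calendar_week = w, session_number = s,
                           value = rpois(n, exp(lp)),
                           stringsAsFactors = FALSE),
       baselines = data.frame(patient_id = sprintf("P%04d",
                                                   seq_len(n_patients)),
                              comm_stratum = factor(stratum,
                                levels = c("1", "2-5", ">=6")),
                              stringsAsFactors = FALSE))
}

# a tiny trial configuration that keeps engine tests fast
small_config <- function(n_patients = 6L, span = 8L, ...) {
  cohort_config(n_patients = n_patients, enrollment_span_weeks = span, ...)
}
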