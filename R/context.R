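# Decision-time state: baseline risk indicators plus dynamic pain summaries
# from the most recent monitored week, carried forward when the patient did
# not respond to IVR assessments.

#' COMM risk stratum from the 8-item baseline score
#'
#' The 8-item Current Opioid Misuse Measure (COMM) scores 0-32 and has no
#' validated clinical cutoffs; patients are grouped into the three
#' roughly equal-sized strata used throughout: scores of 1, 2-5, and >=6.
#' (Eligibility requires a score > 0.)
#'
#' @param comm_score Integer vector of 8-item COMM totals.
#' @return Factor with levels `"1"`, `"2-5"`, `">=6"`.
#' @export
comm_stratum <- function(comm_score) {
  if (any(comm_score < 0 | comm_score > 32, na.rm = TRUE))
    stop("8-item COMM scores must lie in 0-32")
  cut(comm_score, breaks = c(-Inf, 1.5, 5.5, Inf),
      labels = c("1", "2-5", ">=6"))
}

#' Feature map for the bandit context vector
#'
#' Declares the ordered feature set and the fixed standardization constants
#' used to build every context vector. Continuous features are centered and
#' scaled by these constants (not by running statistics) so that a logged
#' run can be replayed decision-for-decision. Centers default to the
#' cohort-level means of the corresponding measures; dynamic priors are the
#' cold-start substitutes used before any monitoring data exists.
#'
#' @param comm_center,comm_scale Centering/scaling for the baseline 8-item
#'   COMM score (defaults 3.7 / 3.4, the cohort mean and SD).
#' @param substances_center,substances_scale For the baseline count of
#'   substances used.
#' @param pain_center,pain_scale For baseline pain on the 0-10 numeric
#'   rating scale (defaults 8.4 / 1.9).
#' @param dyn_pain_center,dyn_pain_scale,dyn_pain_prior For the weekly mean
#'   IVR-reported pain intensity; the prior substitutes when no monitored
#'   week exists yet.
#' @param interference_center,interference_scale,interference_prior For the
#'   weekly mean pain-related interference (asked on no-use days only).
#' @param sessions Protocol length in weekly sessions (12); the ordinal
#'   session number is mapped affinely onto `[0, 1]`.
#' @return An object of class `feature_map`; its `names` field is the
#'   ordered feature list, length 7.
#' @export
feature_map <- function(comm_center = 3.7, comm_scale = 3.4,
                        substances_center = 1.0, substances_scale = 1.0,
                        pain_center = 8.4, pain_scale = 1.9,
                        dyn_pain_center = 5.0, dyn_pain_scale = 2.5,
                        dyn_pain_prior = 5.0,
                        interference_center = 4.0, interference_scale = 2.5,
                        interference_prior = 4.0,
                        sessions = 12L) {
  stopifnot(comm_scale > 0, substances_scale > 0, pain_scale > 0,
            dyn_pain_scale > 0, interference_scale > 0, sessions >= 2)
  structure(list(
    names = c("intercept", "comm", "substances", "baseline_pain",
              "session", "pain_intensity", "pain_interference"),
    comm_center = comm_center, comm_scale = comm_scale,
    substances_center = substances_center,
    substances_scale = substances_scale,
    pain_center = pain_center, pain_scale = pain_scale,
    dyn_pain_center = dyn_pain_center, dyn_pain_scale = dyn_pain_scale,
    dyn_pain_prior = dyn_pain_prior,
    interference_center = interference_center,
    interference_scale = interference_scale,
    interference_prior = interference_prior,
    sessions = as.integer(sessions)),
    class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("Context feature map (", length(x$names), " features): ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the context vector for one weekly decision
#'
#' Combines fixed baseline information (8-item COMM score, number of
#' substances used, baseline pain severity), the patient's ordinal session
#' number, and dynamic pain summaries from the reference week: the most
#' recent week before the decision with at least one completed monitoring
#' call. When the patient failed to respond in the previous week the most
#' recent week with available information is carried forward (`stale =
#' TRUE`); before any monitoring data exists the configured population
#' priors substitute. Pain interference is collected on no-use days only,
#' so a reference week without no-use days also falls back to its prior.
#'
#' @param baseline One-row data frame (or list) with `comm_score`,
#'   `n_substances`, `baseline_pain`.
#' @param weekly_history Data frame of the patient's weekly IVR summaries
#'   before the decision week: columns `calendar_week`, `n_completed_days`,
#'   `pain_mean`, `interference_mean` (see [weekly_ivr_summaries()]). May
#'   have zero rows.
#' @param session_number Ordinal session, 1 to `fmap$sessions`.
#' @param calendar_week Calendar week of the decision; used to flag
#'   staleness of the carried-forward data.
#' @param fmap A [feature_map()].
#' @return List with `features` (named numeric vector, no missing values),
#'   `stale` (TRUE when the dynamic features did not come from the
#'   immediately preceding week), and `source_week` (the reference week, or
#'   `NA` before any monitored week exists).
#' @export
build_context <- function(baseline, weekly_history, session_number,
                          calendar_week, fmap = feature_map()) {
  stopifnot(inherits(fmap, "feature_map"))
  session_number <- as.integer(session_number)
  if (session_number < 1L || session_number > fmap$sessions)
    stop("session_number must lie in 1..", fmap$sessions)

  obs <- weekly_history[
    weekly_history$n_completed_days >= 1L &
      weekly_history$calendar_week < calendar_week, , drop = FALSE]
  if (nrow(obs)) {
    ref <- obs[which.max(obs$calendar_week), , drop = FALSE]
    source_week <- ref$calendar_week
    stale <- source_week < calendar_week - 1L
    pain <- if (is.na(ref$pain_mean)) fmap$dyn_pain_prior else ref$pain_mean
    interference <- if (is.na(ref$interference_mean))
      fmap$interference_prior else ref$interference_mean
  } else {
    source_week <- NA_integer_
    stale <- TRUE
    pain <- fmap$dyn_pain_prior
    interference <- fmap$interference_prior
  }

  features <- c(
    intercept = 1,
    comm = (baseline$comm_score - fmap$comm_center) / fmap$comm_scale,
    substances = (baseline$n_substances - fmap$substances_center) /
      fmap$substances_scale,
    baseline_pain = (baseline$baseline_pain - fmap$pain_center) /
      fmap$pain_scale,
    session = (session_number - 1) / (fmap$sessions - 1),
    pain_intensity = (pain - fmap$dyn_pain_center) / fmap$dyn_pain_scale,
    pain_interference = (interference - fmap$interference_center) /
      fmap$interference_scale)
  if (anyNA(features))
    stop("context features contain missing values after fallback")
  list(features = features, stale = stale,
       source_week = as.integer(source_week))
}

#' Per patient-week monitoring summaries feeding the context vector
#'
#' Summarizes a long daily IVR table into the quantities the context
#' builder consumes: completed-day count, mean reported pain intensity over
#' completed days, and mean pain-related interference over completed no-use
#' days (`NA` when no such day exists).
#'
#' @param daily Long-format daily IVR data frame (see
#'   [weekly_risk_scores()]); a `pain_interference` column is used when
#'   present.
#' @return Data frame with one row per patient-week: `patient_id`,
#'   `calendar_week`, `n_completed_days`, `pain_mean`, `interference_mean`.
#' @export
weekly_ivr_summaries <- function(daily) {
  check_ivr_daily(daily)
  if (!"pain_interference" %in% names(daily))
    daily$pain_interference <- NA_real_
  parts <- split(daily, list(daily$patient_id, daily$calendar_week),
                 drop = TRUE)
  rows <- lapply(parts, function(wk) {
    done <- wk$completed %in% TRUE
    nouse <- done & wk$oa_use_24h %in% FALSE
    data.frame(
      patient_id = wk$patient_id[1L],
      calendar_week = wk$calendar_week[1L],
      n_completed_days = sum(done),
      pain_mean = if (any(done & !is.na(wk$pain_nrs)))
        mean(wk$pain_nrs[done], na.rm = TRUE) else NA_real_,
      interference_mean = if (any(nouse & !is.na(wk$pain_interference)))
        mean(wk$pain_interference[nouse], na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- as.data.frame(data.table::rbindlist(rows))
  out <- out[order(out$patient_id, out$calendar_week), , drop = FALSE]
  rownames(out) <- NULL
  out
}
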