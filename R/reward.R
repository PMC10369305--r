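# Weekly OA risk score: the reward signal of the decision engine.
#
# Daily IVR monitoring yields, per patient-day: a completion flag, pain on
# the 0-10 numeric rating scale, a yes/no report of OA use in the previous
# 24 hours and, on use days only, the three misuse-frequency items
# (1 = "several times", 2 = "once or twice", 3 = "not at all").

ivr_daily_columns <- function() {
  c("patient_id", "calendar_week", "day_index", "completed", "pain_nrs",
    "oa_use_24h", "need", "friend", "symptoms", "pain_interference")
}

check_ivr_daily <- function(daily) {
  need <- setdiff(c("patient_id", "completed", "oa_use_24h", risk_items()),
                  names(daily))
  if (length(need))
    stop("daily IVR data is missing columns: ", paste(need, collapse = ", "))
  for (it in risk_items()) {
    v <- daily[[it]]
    if (any(!is.na(v) & (v < 1 | v > 3)))
      stop("risk item '", it, "' outside its 1-3 coding range")
  }
  invisible(daily)
}

#' Average a misuse item over the days it was asked in a patient-week
#'
#' The weekly value of each misuse item is the arithmetic mean of the
#' patient's responses over the days of that week on which the item was
#' asked, i.e. completed calls reporting OA use in the previous 24 hours.
#' Days without a completed call, and completed no-use days (on which the
#' item is not asked), do not enter the denominator.
#'
#' @param responses Data frame of daily IVR rows for one patient-week, with
#'   at least columns `patient_id`, `completed`, `oa_use_24h` and the item
#'   columns `need`, `friend`, `symptoms` (blank/`NA` cells denote absent).
#' @param item One of `"need"`, `"friend"`, `"symptoms"`.
#' @return The mean response in `[1, 3]`, or `NA_real_` when the item was
#'   asked on zero days.
#' @seealso [compute_weekly_risk_score()]
#' @export
#' @examples
#' wk <- data.frame(patient_id = "P1", completed = TRUE,
#'                  oa_use_24h = TRUE, need = c(1, 2),
#'                  friend = c(3, 3), symptoms = c(2, 2))
#' weekly_item_average(wk, "need")    # 1.5
weekly_item_average <- function(responses, item) {
  item <- match.arg(item, risk_items())
  check_ivr_daily(responses)
  if (nrow(responses) == 0L) return(NA_real_)
  if (length(unique(responses$patient_id)) > 1L)
    stop("responses span more than one patient_id")
  asked <- responses$completed %in% TRUE &
    responses$oa_use_24h %in% TRUE &
    !is.na(responses[[item]])
  if (!any(asked)) return(NA_real_)
  mean(responses[[item]][asked])
}

#' Compute the weekly OA risk score for one patient-week
#'
#' The score ranges from 1 to 7 with higher values indicating greater
#' opioid-analgesic risk. A patient-week in which no completed call reported
#' OA use scores 1, the best possible value. For weeks with reported use,
#'
#' \deqn{\mathrm{score} = 7 - [(\bar s_{need}-1) + (\bar s_{friend}-1) +
#'   (\bar s_{symptoms}-1)]}
#'
#' where each \eqn{\bar s} is the item's weekly average over the days it was
#' asked ([weekly_item_average()]); each item can contribute up to 2 points.
#' All items at "several times" (coded 1) give the maximum score 7; all at
#' "not at all" (coded 3) give 1. A use-week item asked on zero days is
#' treated as "not at all" (average 3), the conservative choice that keeps
#' the score defined. Weeks with zero completed calls have no score.
#'
#' @param responses Data frame of daily IVR rows for one patient-week
#'   (see [weekly_item_average()] for required columns).
#' @return A one-row data frame with columns `patient_id`, `calendar_week`
#'   (if present in the input), `value`, `n_completed_days`, `any_oa_use`;
#'   or `NULL` when the week has no completed call.
#' @export
#' @examples
#' wk <- data.frame(patient_id = "P1", completed = TRUE,
#'                  oa_use_24h = FALSE, need = NA_real_,
#'                  friend = NA_real_, symptoms = NA_real_)[rep(1, 4), ]
#' compute_weekly_risk_score(wk)$value   # 1: no pills taken all week
compute_weekly_risk_score <- function(responses) {
  check_ivr_daily(responses)
  if (nrow(responses) && length(unique(responses$patient_id)) > 1L)
    stop("responses span more than one patient_id")
  done <- responses[responses$completed %in% TRUE, , drop = FALSE]
  n_days <- nrow(done)
  if (n_days == 0L) return(NULL)
  any_use <- any(done$oa_use_24h %in% TRUE)
  if (!any_use) {
    value <- 1
  } else {
    avgs <- vapply(risk_items(), function(it)
      weekly_item_average(responses, it), numeric(1))
    avgs[is.na(avgs)] <- 3   # unasked item: no penalty
    value <- 7 - sum(avgs - 1)
  }
  out <- data.frame(patient_id = responses$patient_id[1L],
                    value = value,
                    n_completed_days = n_days,
                    any_oa_use = any_use,
                    stringsAsFactors = FALSE)
  if ("calendar_week" %in% names(responses))
    out <- cbind(out[1L], calendar_week = responses$calendar_week[1L],
                 out[-1L])
  out
}

#' Weekly risk scores for a long table of daily IVR responses
#'
#' Applies [compute_weekly_risk_score()] to every patient-week in a
#' long-format daily monitoring table; patient-weeks without any completed
#' call are dropped (their score is undefined).
#'
#' @param daily Data frame with one row per patient-day: `patient_id`,
#'   `calendar_week`, `day_index`, `completed`, `pain_nrs`, `oa_use_24h`,
#'   `need`, `friend`, `symptoms` (blank cells denote absent).
#' @return Data frame with one row per scored patient-week: `patient_id`,
#'   `calendar_week`, `value`, `n_completed_days`, `any_oa_use`.
#' @export
weekly_risk_scores <- function(daily) {
  check_ivr_daily(daily)
  if (!"calendar_week" %in% names(daily))
    stop("daily IVR data needs a calendar_week column")
  parts <- split(daily, list(daily$patient_id, daily$calendar_week),
                 drop = TRUE)
  rows <- lapply(parts, compute_weekly_risk_score)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(patient_id = character(), calendar_week = integer(),
                      value = numeric(), n_completed_days = integer(),
                      any_oa_use = logical()))
  out <- as.data.frame(data.table::rbindlist(rows))
  out <- out[order(out$patient_id, out$calendar_week), , drop = FALSE]
  rownames(out) <- NULL
  out
}
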