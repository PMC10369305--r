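# Trial orchestration. Patients enter at staggered calendar weeks across
# the enrollment span; every active patient receives exactly one session
# decision per calendar week for 12 weeks. Within a calendar week all
# decisions are made first (using monitoring data from strictly earlier
# weeks), the week's monitoring is then observed, and finally the previous
# week's decisions are credited with the negated risk score observed this
# week (the decision targets *future* risk). Weeks whose reward is never
# observed (no completed call, or a session-12 decision whose follow-up
# week is past the monitoring window) are logged but skipped at update
# time, never imputed.

#' Run a complete closed-loop simulated trial
#'
#' Samples a cohort, enrolls it on a rolling schedule (uniform arrivals by
#' default), and drives the weekly decide / monitor / update loop with one
#' shared LinUCB state pooled across patients.
#'
#' @param config A [cohort_config()] describing the cohort and the
#'   generative environment.
#' @param alpha LinUCB exploration width (default 1).
#' @param tie_tol Relative tie tolerance passed to [linucb()].
#' @param fmap A [feature_map()]; its dimension fixes the bandit's.
#' @param seed Integer seed; governs cohort sampling, the environment and
#'   the tie-randomization stream. The same seed reproduces the run
#'   byte-for-byte.
#' @return Object of class `oabandit_trial`: list with `decisions` (one
#'   row per weekly decision: identifiers, context features `f_*`,
#'   staleness, per-arm UCBs, chosen arm, tie flag, delivery, and the
#'   realized next-week risk score `reward_observed`, `NA` when
#'   unobserved), `scores` (weekly risk scores), `daily` (all daily IVR
#'   rows), `cohort` (baselines with `entry_week`), `state` (final bandit),
#'   plus `config`, `alpha`, `fmap` and `seed`.
#' @export
#' @examples
#' run <- run_trial(cohort_config(n_patients = 4, enrollment_span_weeks = 6),
#'                  seed = 1)
#' nrow(run$decisions)  # 4 patients x 12 sessions = 48
run_trial <- function(config = cohort_config(), alpha = 1, tie_tol = 1e-9,
                      fmap = feature_map(sessions = config$sessions),
                      seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), inherits(fmap, "feature_map"))
  set.seed(seed)
  cohort <- sample_cohort(config)
  n <- nrow(cohort)
  d <- length(fmap$names)
  state <- linucb(d = d, alpha = alpha, tie_tol = tie_tol, seed = seed)
  if (n == 0L)
    return(structure(list(decisions = data.frame(), scores = data.frame(),
                          daily = data.frame(), cohort = cohort,
                          state = state, config = config, alpha = alpha,
                          fmap = fmap, seed = seed),
                     class = "oabandit_trial"))
  cohort$entry_week <- sort(sample.int(config$enrollment_span_weeks, n,
                                       replace = TRUE))
  pstates <- lapply(seq_len(n), function(i)
    init_patient_state(cohort[i, ], config))
  histories <- vector("list", n)          # per patient: weekly summaries
  last_decision <- vector("list", n)      # pending reward from week t-1
  decisions <- vector("list", n * config$sessions)
  daily_all <- vector("list", n * config$sessions)
  scores <- vector("list", n * config$sessions)
  rec_i <- 0L

  horizon <- config$enrollment_span_weeks + config$sessions - 1L
  for (cw in seq_len(horizon)) {
    active <- which(cohort$entry_week <= cw &
                      cw <= cohort$entry_week + config$sessions - 1L)
    if (!length(active)) next

    # phase 1: all decisions, from information strictly before week cw
    week_sel <- vector("list", length(active))
    for (j in seq_along(active)) {
      i <- active[j]
      session <- cw - cohort$entry_week[i] + 1L
      hist <- if (is.null(histories[[i]]))
        data.frame(calendar_week = integer(), n_completed_days = integer(),
                   pain_mean = numeric(), interference_mean = numeric())
      else data.table::rbindlist(histories[[i]])
      ctx <- build_context(cohort[i, ], hist, session, cw, fmap)
      sel <- select_arm(state, ctx$features)
      state <- sel$state
      week_sel[[j]] <- list(i = i, session = session, ctx = ctx, sel = sel)
    }

    # phase 2: monitoring and session delivery for week cw
    for (j in seq_along(active)) {
      w <- week_sel[[j]]; i <- w$i
      sim <- simulate_patient_week(pstates[[i]], cohort[i, ], w$session,
                                   w$sel$arm, config)
      pstates[[i]] <- sim$pstate
      day <- sim$daily
      day <- cbind(patient_id = cohort$patient_id[i], calendar_week = cw,
                   day, stringsAsFactors = FALSE)
      sc <- compute_weekly_risk_score(day)
      done <- day$completed
      nouse <- done & day$oa_use_24h %in% FALSE
      histories[[i]] <- c(histories[[i]], list(data.frame(
        calendar_week = cw, n_completed_days = sum(done),
        pain_mean = if (any(done)) mean(day$pain_nrs[done]) else NA_real_,
        interference_mean = if (any(nouse))
          mean(day$pain_interference[nouse]) else NA_real_)))

      rec_i <- rec_i + 1L
      feats <- as.list(w$ctx$features)
      names(feats) <- paste0("f_", names(w$ctx$features))
      decisions[[rec_i]] <- c(
        list(patient_id = cohort$patient_id[i], calendar_week = cw,
             session_number = w$session),
        feats,
        list(stale = w$ctx$stale, source_week = w$ctx$source_week),
        setNames(as.list(w$sel$ucb), paste0("ucb_", names(w$sel$ucb))),
        list(chosen_arm = w$sel$arm, tie_flag = w$sel$tie_flag,
             delivered = sim$delivered, reward_observed = NA_real_))
      daily_all[[rec_i]] <- day
      if (!is.null(sc))
        scores[[rec_i]] <- cbind(sc, session_number = w$session)
      # queue for the update phase of week cw+1
      this_score <- if (is.null(sc)) NA_real_ else sc$value
      prev <- last_decision[[i]]
      # phase 3 (interleaved per patient): credit week cw-1's decision
      # with this week's observed score
      if (!is.null(prev) && !is.na(this_score)) {
        state <- linucb_update(state, prev$arm, prev$x, -this_score)
        decisions[[prev$rec_i]]$reward_observed <- this_score
      }
      last_decision[i] <- list(if (w$session < config$sessions)
        list(arm = w$sel$arm, x = w$ctx$features, rec_i = rec_i))
    }
  }

  decisions <- as.data.frame(data.table::rbindlist(
    lapply(decisions[seq_len(rec_i)], as.data.frame)))
  daily <- as.data.frame(data.table::rbindlist(daily_all[seq_len(rec_i)]))
  scores <- scores[!vapply(scores, is.null, logical(1))]
  scores <- if (length(scores))
    as.data.frame(data.table::rbindlist(scores))
  else data.frame(patient_id = character(), calendar_week = integer(),
                  value = numeric(), n_completed_days = integer(),
                  any_oa_use = logical(), session_number = integer())
  structure(list(decisions = decisions, scores = scores, daily = daily,
                 cohort = cohort, state = state, config = config,
                 alpha = alpha, fmap = fmap, seed = seed),
            class = "oabandit_trial")
}

#' @export
print.oabandit_trial <- function(x, ...) {
  cat("Simulated adaptive trial:", nrow(x$cohort), "patients,",
      nrow(x$decisions), "decisions, seed", x$seed, "\n")
  if (nrow(x$decisions)) {
    tab <- table(x$decisions$chosen_arm)[arm_levels()]
    cat("decision mix:",
        paste(sprintf("%s %.1f%%", arm_levels(),
                      100 * as.numeric(tab) / nrow(x$decisions)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a trial run to an audit directory
#'
#' Emits `decisions.csv`, `weekly_scores.csv`, `daily_ivr.csv`,
#' `baselines.csv`, the final bandit snapshot `state.json`, and
#' `manifest.json` (config, seed, and an md5 content hash of
#' decisions.csv).
#'
#' @param run An [run_trial()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "oabandit_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$decisions, file.path(dir, "decisions.csv"),
            row.names = FALSE)
  write.csv(run$scores, file.path(dir, "weekly_scores.csv"),
            row.names = FALSE)
  write.csv(run$daily, file.path(dir, "daily_ivr.csv"), row.names = FALSE)
  write.csv(run$cohort, file.path(dir, "baselines.csv"), row.names = FALSE)
  linucb_save(run$state, file.path(dir, "state.json"))
  cfg <- run$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(package = "oabandit", seed = run$seed, alpha = run$alpha,
         config = cfg,
         decisions_md5 = unname(tools::md5sum(
           file.path(dir, "decisions.csv")))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replay a logged run through a fresh policy
#'
#' Feeds the logged contexts and observed rewards of a trial through a
#' fresh LinUCB state in the engine's calendar order and checks that every
#' logged arm choice is reproduced exactly. This is the audit guarantee:
#' decisions are a deterministic function of the log itself (contexts,
#' rewards, seed), with no hidden state.
#'
#' @param run An [run_trial()] result.
#' @return List with `identical` (logical), `n_mismatch` and `replayed`
#'   (the replayed arm choices, in log order).
#' @export
replay_trial <- function(run) {
  stopifnot(inherits(run, "oabandit_trial"))
  dec <- run$decisions
  fcols <- paste0("f_", run$fmap$names)
  state <- linucb(d = length(fcols), alpha = run$alpha,
                  tie_tol = run$state$tie_tol, seed = run$seed)
  replayed <- character(nrow(dec))
  pending <- list()   # per patient: last decision awaiting reward
  for (cw in sort(unique(dec$calendar_week))) {
    rows <- which(dec$calendar_week == cw)
    # all of this week's decisions first ...
    for (r in rows) {
      sel <- select_arm(state, as.numeric(dec[r, fcols]))
      state <- sel$state
      replayed[r] <- sel$arm
    }
    # ... then the previous week's decisions are credited with the rewards
    # observed this week, in the same patient order as the engine
    for (r in rows) {
      pid <- dec$patient_id[r]
      prev <- pending[[pid]]
      if (!is.null(prev) && !is.na(dec$reward_observed[prev]))
        state <- linucb_update(state, dec$chosen_arm[prev],
                               as.numeric(dec[prev, fcols]),
                               -dec$reward_observed[prev])
      pending[[pid]] <- r
    }
  }
  list(identical = identical(replayed, dec$chosen_arm),
       n_mismatch = sum(replayed != dec$chosen_arm),
       replayed = replayed)
}
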