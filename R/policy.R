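# LinUCB contextual bandit over the three session types, pooled across
# patients. One shared state serves the whole trial: per arm, a ridge
# design matrix A (initialized to the identity, prior lambda = 1) and a
# response accumulator b. The internal reward is the NEGATED weekly OA risk
# score, so maximizing the upper confidence bound minimizes expected risk.

#' Create a LinUCB bandit state
#'
#' Per-arm disjoint linear model with a ridge prior: `A = I_d`, `b = 0`.
#' The upper confidence bound of arm \eqn{a} at context \eqn{x} is
#' \deqn{\hat\theta_a^\top x + \alpha \sqrt{x^\top A_a^{-1} x}, \qquad
#'   \hat\theta_a = A_a^{-1} b_a.}
#' Exact-tie handling conserves counselor time: a counselor/IVR tie at the
#' maximum resolves to the IVR arm; a brief/extended IVR tie resolves
#' uniformly at random. Tie randomization draws from a dedicated
#' counter-based stream (recorded seed + draw counter), so replaying a
#' logged run reproduces every choice bit-for-bit.
#'
#' @param d Feature dimension (length of the context vector).
#' @param alpha Exploration width \eqn{\alpha > 0}; default 1.
#' @param arms Character vector of arm labels; default [arm_levels()].
#' @param tie_tol Relative tolerance within which UCB scores count as tied
#'   (default 1e-9; exact float ties are fragile).
#' @param seed Integer seed for the tie-randomization stream.
#' @return Object of class `linucb`.
#' @export
#' @examples
#' st <- linucb(d = 7)
#' ucb_score(st, "counselor", c(1, rep(0, 6)))  # cold start: alpha * 1
linucb <- function(d, alpha = 1, arms = arm_levels(), tie_tol = 1e-9,
                   seed = 1L) {
  stopifnot(d >= 1, alpha >= 0, length(arms) >= 2, tie_tol >= 0)
  structure(list(
    d = as.integer(d), alpha = alpha, arms = arms, tie_tol = tie_tol,
    A = setNames(lapply(arms, function(a) diag(d)), arms),
    b = setNames(lapply(arms, function(a) numeric(d)), arms),
    n_updates = setNames(integer(length(arms)), arms),
    seed = as.integer(seed), tie_count = 0L),
    class = "linucb")
}

#' @export
print.linucb <- function(x, ...) {
  cat("LinUCB bandit: d =", x$d, ", alpha =", x$alpha, "\n")
  cat("updates per arm:",
      paste(sprintf("%s=%d", x$arms, x$n_updates), collapse = ", "), "\n")
  invisible(x)
}

check_context_x <- function(state, x) {
  x <- as.numeric(x)
  if (length(x) != state$d)
    stop("context length ", length(x), " does not match bandit dimension ",
         state$d)
  if (anyNA(x) || any(!is.finite(x)))
    stop("context vector contains non-finite values")
  x
}

#' Ridge point estimate for one arm
#'
#' @param state A [linucb()] state.
#' @param arm Arm label.
#' @return \eqn{\hat\theta_a = A_a^{-1} b_a}, the penalized least-squares
#'   coefficient vector (ridge penalty \eqn{\lambda = 1}).
#' @export
theta_hat <- function(state, arm) {
  arm <- match.arg(arm, state$arms)
  as.numeric(solve(state$A[[arm]], state$b[[arm]]))
}

#' Upper confidence bound of one arm at a context
#'
#' @inheritParams theta_hat
#' @param x Numeric context vector of length `state$d`.
#' @return \eqn{\hat\theta_a^\top x + \alpha\sqrt{x^\top A_a^{-1}x}}.
#' @export
ucb_score <- function(state, arm, x) {
  arm <- match.arg(arm, state$arms)
  x <- check_context_x(state, x)
  Ainv_x <- solve(state$A[[arm]], x)
  sum(theta_hat(state, arm) * x) + state$alpha * sqrt(sum(x * Ainv_x))
}

# deterministic uniform draw from the tie stream, leaving the global RNG
# untouched
tie_runif <- function(seed, counter) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((abs(as.double(seed)) * 48271 + as.double(counter)) %% 2147483647)
  runif(1)
}

#' Select the arm for one weekly decision
#'
#' Computes the UCB of every arm and returns the maximizer, applying the
#' counselor-conserving tie rules: if the counselor arm ties (within the
#' state's relative tolerance) with the best IVR arm, the IVR arm is
#' chosen; if the brief and extended IVR arms tie at the maximum, one is
#' chosen uniformly at random from the tie stream. Under an exact
#' three-way tie the counselor arm is therefore never selected.
#'
#' @inheritParams ucb_score
#' @return List with `arm` (chosen label), `tie_flag` (`"none"`,
#'   `"counselor_conserved"`, `"ivr_random"`, or
#'   `"counselor_conserved+ivr_random"`), `ucb` (named numeric vector of
#'   all arm scores) and `state` (the input state with its tie-draw counter
#'   advanced; thread it through subsequent calls for replayability).
#' @export
select_arm <- function(state, x) {
  x <- check_context_x(state, x)
  ucb <- vapply(state$arms, function(a) ucb_score(state, a, x), numeric(1))
  tol <- state$tie_tol * max(1, max(abs(ucb)))
  tied <- names(ucb)[ucb >= max(ucb) - tol]
  flag <- "none"
  ivr <- setdiff(tied, "counselor")
  if ("counselor" %in% tied && length(ivr)) {
    tied <- ivr
    flag <- "counselor_conserved"
  }
  if (length(tied) > 1L) {
    state$tie_count <- state$tie_count + 1L
    u <- tie_runif(state$seed, state$tie_count)
    arm <- tied[1L + (u >= 0.5)]
    flag <- if (flag == "none") "ivr_random"
            else paste0(flag, "+ivr_random")
  } else {
    arm <- tied[1L]
  }
  list(arm = arm, tie_flag = flag, ucb = ucb, state = state)
}

#' Observe a reward and update one arm's linear model
#'
#' Rank-one update of the assigned arm only: `A <- A + x x^T`,
#' `b <- b + reward * x`. The reward is the negated weekly OA risk score
#' observed the week after the decision, so it lies in `[-7, -1]`; updates
#' are applied for the assigned arm whether or not a counselor session was
#' completed (intention-to-treat).
#'
#' @inheritParams ucb_score
#' @param reward Finite numeric scalar (internal reward scale).
#' @return The updated `linucb` state.
#' @export
linucb_update <- function(state, arm, x, reward) {
  arm <- match.arg(arm, state$arms)
  x <- check_context_x(state, x)
  if (length(reward) != 1L || !is.finite(reward))
    stop("reward must be a single finite number")
  state$A[[arm]] <- state$A[[arm]] + tcrossprod(x)
  state$b[[arm]] <- state$b[[arm]] + reward * x
  state$n_updates[[arm]] <- state$n_updates[[arm]] + 1L
  state
}

#' Empirical arm-selection frequencies over a set of contexts
#'
#' Runs [select_arm()] (without updating) across a context set, Monte-Carlo
#' averaging over the tie randomness, and returns the per-arm frequencies
#' of the chosen arm. The caller's state is not modified.
#'
#' @inheritParams ucb_score
#' @param contexts Numeric matrix, one context per row (`ncol == state$d`).
#' @param draws Number of Monte-Carlo passes over the context set.
#' @return Named numeric vector of frequencies, summing to exactly 1.
#' @export
selection_probabilities <- function(state, contexts, draws = 1L) {
  contexts <- as.matrix(contexts)
  if (!nrow(contexts)) stop("contexts must be nonempty")
  counts <- setNames(numeric(length(state$arms)), state$arms)
  st <- state
  for (r in seq_len(draws)) {
    for (i in seq_len(nrow(contexts))) {
      sel <- select_arm(st, contexts[i, ])
      st <- sel$state
      counts[sel$arm] <- counts[sel$arm] + 1
    }
  }
  counts / sum(counts)
}

#' Serialize a bandit state to a versioned JSON snapshot
#'
#' Matrices are stored row-major; the tie-stream seed and counter are kept
#' so that a restored state continues the exact randomization sequence.
#'
#' @param state A [linucb()] state.
#' @param path File path for the JSON snapshot.
#' @return `path`, invisibly.
#' @seealso [linucb_load()]
#' @export
linucb_save <- function(state, path) {
  snap <- list(
    format = "oabandit/linucb", version = 1L,
    d = state$d, alpha = state$alpha, arms = state$arms,
    tie_tol = state$tie_tol, seed = state$seed,
    tie_count = state$tie_count,
    n_updates = as.list(state$n_updates),
    A = lapply(state$A, function(m) as.numeric(t(m))),
    b = state$b)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a bandit state from a JSON snapshot
#'
#' @param path Path written by [linucb_save()].
#' @return The restored `linucb` state.
#' @export
linucb_load <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(snap$format, "oabandit/linucb"))
    stop("not a LinUCB snapshot: ", path)
  st <- linucb(d = snap$d, alpha = snap$alpha, arms = snap$arms,
               tie_tol = snap$tie_tol, seed = snap$seed)
  st$tie_count <- as.integer(snap$tie_count)
  st$n_updates <- setNames(as.integer(unlist(snap$n_updates[snap$arms])),
                           snap$arms)
  for (a in snap$arms) {
    st$A[[a]] <- matrix(snap$A[[a]], nrow = snap$d, byrow = TRUE)
    st$b[[a]] <- as.numeric(snap$b[[a]])
  }
  st
}
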