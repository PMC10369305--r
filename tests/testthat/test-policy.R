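# LinUCB: scores, tie rules, updates, serialization, regret.

e_vec <- function(i, d) { x <- numeric(d); x[i] <- 1; x }

test_that("cold-start UCB is alpha for any unit-norm context", {
  st <- linucb(d = 3, alpha = 1)
  expect_equal(ucb_score(st, "brief_ivr", e_vec(1, 3)), 1)
  x <- c(1, 2, -2) / 3
  expect_equal(ucb_score(st, "counselor", x), 1)
  st2 <- linucb(d = 3, alpha = 0.5)
  expect_equal(ucb_score(st2, "extended_ivr", x), 0.5)
})

test_that("UCB after one update matches hand linear algebra", {
  st <- linucb(d = 3, alpha = 1)
  st <- linucb_update(st, "brief_ivr", e_vec(1, 3), -2)
  # A = diag(2,1,1), b = (-2,0,0) => theta = (-1,0,0); at x = e1:
  # UCB = -1 + sqrt(1/2)
  expect_equal(theta_hat(st, "brief_ivr"), c(-1, 0, 0))
  expect_equal(ucb_score(st, "brief_ivr", e_vec(1, 3)), -1 + sqrt(0.5))
  # untouched arms keep the prior
  expect_equal(theta_hat(st, "counselor"), c(0, 0, 0))
  # alpha = 0 reduces to the ridge point estimate
  st$alpha <- 0
  expect_equal(ucb_score(st, "brief_ivr", e_vec(1, 3)), -1)
})

test_that("updates are input-checked, commute, and ignore zero contexts", {
  st <- linucb(d = 4)
  expect_error(linucb_update(st, "brief_ivr", e_vec(1, 4), NaN), "finite")
  expect_error(ucb_score(st, "brief_ivr", c(1, 2)), "dimension")

  st0 <- linucb_update(st, "counselor", numeric(4), -3)
  expect_equal(st0$A, st$A)
  expect_equal(st0$b, st$b)

  set.seed(1)
  x1 <- rnorm(4); x2 <- rnorm(4)
  a <- linucb_update(linucb_update(st, "brief_ivr", x1, -2),
                     "brief_ivr", x2, -5)
  b <- linucb_update(linucb_update(st, "brief_ivr", x2, -5),
                     "brief_ivr", x1, -2)
  expect_equal(a$A, b$A)
  expect_equal(a$b, b$b)
})

test_that("per-arm estimates equal the penalized least-squares oracle", {
  set.seed(11)
  st <- linucb(d = 5)
  X <- matrix(rnorm(60 * 5), 60)
  y <- rnorm(60, -3, 1)
  for (i in 1:60) {
    arm <- arm_levels()[(i %% 3) + 1L]
    st <- linucb_update(st, arm, X[i, ], y[i])
  }
  for (k in 0:2) {
    arm <- arm_levels()[k + 1L]
    idx <- which((seq_len(60) %% 3) == k)
    expect_equal(theta_hat(st, arm),
                 as.numeric(oracle_ridge(X[idx, ], y[idx])),
                 tolerance = 1e-10)
  }
})

test_that("tie rules conserve counselor time and split IVR ties evenly", {
  st <- linucb(d = 3)
  # rig exact per-arm UCBs: alpha = 0, A = 1, b = target, so UCB = b * x
  rig <- function(ucbs) {
    s <- linucb(d = 1, alpha = 0)
    for (k in seq_along(arm_levels())) {
      s$A[[k]] <- matrix(1)
      s$b[[k]] <- ucbs[k]
    }
    s
  }
  sel <- select_arm(rig(c(0.2, 0.4, 0.9)), 1)
  expect_identical(sel$arm, "counselor")
  expect_identical(sel$tie_flag, "none")

  sel <- select_arm(rig(c(0.7, 0.3, 0.7)), 1)
  expect_identical(sel$arm, "brief_ivr")
  expect_identical(sel$tie_flag, "counselor_conserved")

  # exact three-way tie: never counselor, brief/extended about half-half
  st3 <- rig(c(0.5, 0.5, 0.5))
  picks <- character(400)
  for (i in 1:400) {
    sel <- select_arm(st3, 1)
    st3 <- sel$state
    picks[i] <- sel$arm
    expect_identical(sel$tie_flag, "counselor_conserved+ivr_random")
  }
  expect_false(any(picks == "counselor"))
  f <- mean(picks == "brief_ivr")
  expect_lt(abs(f - 0.5), 4 * sqrt(0.25 / 400))
})

test_that("cold-start selection splits evenly between the IVR arms", {
  st <- linucb(d = 3)
  X <- matrix(rep(c(1, 0.5, -0.5), 50), ncol = 3, byrow = TRUE)
  freq <- selection_probabilities(st, X, draws = 20)
  expect_equal(sum(freq), 1)
  expect_identical(unname(freq["counselor"]), 0)
  expect_lt(abs(freq[["brief_ivr"]] - 0.5), 0.1)
})

test_that("heavily penalized counselor rewards lower its selection share", {
  set.seed(21)
  st <- linucb(d = 3)
  X <- cbind(1, matrix(rnorm(80 * 2), 80))
  cold <- selection_probabilities(st, X, draws = 5)
  for (i in 1:40) st <- linucb_update(st, "counselor",
                                      c(1, rnorm(2)), -6.5)
  warm <- selection_probabilities(st, X, draws = 5)
  expect_lt(warm[["counselor"]], cold[["counselor"]] + 1e-12)
  expect_equal(sum(warm), 1)
})

test_that("the ridge floor keeps every arm's design matrix well-posed", {
  set.seed(31)
  st <- linucb(d = 4)
  for (i in 1:30)
    st <- linucb_update(st, sample(arm_levels(), 1), rnorm(4), runif(1, -7, -1))
  for (a in arm_levels()) {
    ev <- eigen(st$A[[a]], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1 - 1e-10)
    expect_equal(st$A[[a]], t(st$A[[a]]))   # symmetry preserved
  }
})

test_that("LinUCB beats a uniform-random policy in a linear environment", {
  set.seed(99)
  d <- 4
  theta <- list(brief_ivr = c(-2, 0.3, 0, 0.2),
                extended_ivr = c(-2.4, -0.2, 0.3, 0),
                counselor = c(-3, 0.1, -0.3, 0.4))
  draw_reward <- function(arm, x) sum(theta[[arm]] * x) + rnorm(1, 0, 0.3)
  st <- linucb(d = d, alpha = 1, seed = 99)
  tot_lin <- 0; tot_unif <- 0
  for (i in 1:2000) {
    x <- c(1, rnorm(d - 1))
    sel <- select_arm(st, x)
    st <- sel$state
    r <- draw_reward(sel$arm, x)
    st <- linucb_update(st, sel$arm, x, r)
    tot_lin <- tot_lin + r
    tot_unif <- tot_unif + draw_reward(sample(arm_levels(), 1), x)
  }
  expect_gt(tot_lin / 2000, tot_unif / 2000)
})

test_that("JSON snapshots round-trip the full state", {
  set.seed(41)
  st <- linucb(d = 6, alpha = 0.7, tie_tol = 1e-8, seed = 17)
  for (i in 1:25)
    st <- linucb_update(st, sample(arm_levels(), 1), rnorm(6),
                        -runif(1, 1, 7))
  sel <- select_arm(st, rnorm(6)); st <- sel$state
  path <- withr::local_tempfile(fileext = ".json")
  linucb_save(st, path)
  st2 <- linucb_load(path)
  expect_equal(st2$A, st$A)
  expect_equal(st2$b, st$b)
  expect_identical(st2$tie_count, st$tie_count)
  expect_identical(st2$n_updates, st$n_updates)
  # restored state continues the same decision stream
  x <- c(1, 1, 1, 0, 0, 0)
  expect_identical(select_arm(st, x)$arm, select_arm(st2, x)$arm)
})
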