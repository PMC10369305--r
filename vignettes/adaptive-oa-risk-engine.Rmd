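---
title: "Adaptive allocation of opioid-risk counseling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive allocation of opioid-risk counseling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oabandit)
```

## The problem

Patients discharged from the emergency department (ED) with pain and any
recent opioid-analgesic (OA) misuse can benefit from risk-reduction
counseling, but live counselors are scarce and most patients are at low
risk. `oabandit` implements a closed-loop decision engine for this
setting: every week, for every enrolled patient, it chooses one of three
session types — a brief (<5 min) automated IVR call, an extended
(5–10 min) IVR call, or a 20-minute live counselor call — with the goal of
minimizing the patient's *future* self-reported OA risk while conserving
counselor time. Learning is pooled across patients: one shared policy
serves the whole caseload, so experience with early enrollees improves
decisions for later ones.

Because no patient-level data from such trials is publicly deposited, the
package pairs the engine with a synthetic cohort simulator calibrated to
published marginal statistics, so the full loop — monitoring, scoring,
allocation, learning, evaluation — is testable end to end.

## The weekly OA risk score (the reward)

Daily IVR monitoring (up to 5 calls/week) collects pain on the 0–10
numeric rating scale and a yes/no report of OA pill use in the previous
24 hours. On use days, three misuse-frequency items are asked, each coded
1 = "several times", 2 = "once or twice", 3 = "not at all": needing more
medication than prescribed (*need*), taking someone else's medication
(*friend*), and using medication for other symptoms (*symptoms*). Item
responses are averaged over the days of the week on which they were asked,
and the weekly score is

$$\mathrm{score} \;=\; 7 - \left[(\bar s_{need}-1) + (\bar s_{friend}-1) +
(\bar s_{symptoms}-1)\right] \in [1, 7],$$

with higher scores indicating greater risk. A week in which no completed
call reported OA use scores 1, the best possible value; a week with zero
completed calls has no score. Three conventions close gaps the scoring
rule leaves open:

* **Denominators.** Item averages run over *asked* days only (completed
  calls with reported use); missed days are never imputed.
* **Partially asked items.** If use occurred but an item was asked on zero
  days, that item is treated as "not at all" (average 3), adding no risk —
  the conservative choice that keeps the score defined.
* **`any_oa_use`.** A single use day makes the week a use week; the
  score-1 rule applies only to weeks with *no* reported pills.

Scores are kept at full precision; nothing is rounded.

## The decision policy: LinUCB with counselor-conserving ties

The engine treats each week's choice as a contextual bandit problem with
three arms. For each arm $a$ it maintains a ridge design matrix
$A_a = I_d + \sum x x^\top$ and response accumulator
$b_a = \sum r\,x$ over the decisions assigned to that arm, giving the
penalized least-squares estimate $\hat\theta_a = A_a^{-1} b_a$
(ridge prior $\lambda = 1$). The arm maximizing the upper confidence bound

$$\mathrm{UCB}_a(x) \;=\; \hat\theta_a^\top x +
\alpha \sqrt{x^\top A_a^{-1} x}$$

is selected. The internal reward is the **negated** weekly risk score
(so maximizing UCB minimizes expected risk), and rewards therefore lie in
$[-7, -1]$.

Ties are resolved to conserve counselor time: if the counselor arm ties
(within a relative tolerance of $10^{-9}$) with the best IVR arm, the IVR
arm is taken; if the two IVR arms tie at the maximum, one is drawn
uniformly at random. Under a cold start all three arms are exactly tied
at every context, so the counselor arm is *never* chosen before any
feedback arrives; its share rises only as updates differentiate the arms.
The tolerance exists because exact floating-point ties are fragile; it is
config-exposed (`tie_tol`).

Design choices the deployment description leaves open, decided here:

* **Reward timing.** The decision made in week $t$ is credited with the
  risk score observed in week $t+1$ (the decision targets future risk).
  If week $t+1$ has no completed calls the update is skipped, never
  imputed. Week-12 decisions have no monitored follow-up week and are
  never updated.
* **Intention to treat.** Updates credit the *assigned* arm whether or not
  an assigned counselor session was completed; the delivery flag is
  logged. This is what makes the counselor arm's completion rate part of
  its realized effectiveness.
* **Batching.** Within a calendar week, all decisions are made first
  (from strictly earlier data), then the previous week's decisions are
  credited — preventing within-week ordering artifacts and information
  leakage.
* **Exploration width.** $\alpha = 1$ by default; no published value
  exists. No discounting or windowing of old observations is applied.
* **Tie randomness.** Tie draws come from a dedicated counter-based
  stream (recorded seed + draw counter), not the global RNG, so a logged
  run replays bit-for-bit from the log alone (`replay_trial()` verifies
  this).

## The context vector

Each decision sees a 7-feature state: an intercept; the baseline 8-item
COMM score, number of substances used, and baseline pain severity
(each centered and scaled by *fixed* constants, defaults 3.7/3.4, 1.0/1.0
and 8.4/1.9, from the cohort-level means); the ordinal session number
mapped onto $[0,1]$; and two dynamic summaries of the reference week —
mean reported pain intensity and mean pain-related interference. The
reference week is the most recent week before the decision with at least
one completed call; when the previous week was unmonitored the engine
carries the most recent available week forward (flagged `stale`), and
before any monitoring exists the configured population priors substitute.
Interference is asked on no-use days only, so a reference week without
no-use days also falls back to its prior. Standardization by fixed
constants (rather than running statistics) keeps logged runs replayable;
whether the deployed system standardized at all is unpublished, so the
feature map is a config-driven registry (`feature_map()`) and alternates
are pluggable.

## The synthetic cohort

`cohort_config()` defaults encode the study conditions: 228 patients in
baseline COMM strata 1 / 2–5 / ≥6 with probabilities 65/228, 115/228,
48/228 (stratum scores: exactly 1; weighted 2–5 with mean 3.0; 6 plus a
negative-binomial shift with mean 9.0, SD ≈ 3.5, capped at 32); age 40.4
(SD 12.7) truncated to 18–70; 66.7% women; 76.8% chronic pain; baseline
pain 8.4 (SD 1.9); rolling uniform enrollment over 130 calendar weeks;
12 weekly sessions each. Engagement: weekly ≥1-call completion declines
linearly from 89.5% (session 1) to 65.9% (session 12); conditional daily
completion is set so that 51.03% of all scheduled call-days complete;
58.6% of assigned counselor sessions are completed, while IVR sessions
always deliver.

Behavior follows a latent misuse propensity $L$ (log-odds of daily OA
use): $L_1 = -0.9 + 0.15\,(\mathrm{COMM} - 3.7) + \epsilon$, evolving as
$L_{w+1} = L_w + \text{effect(delivered arm)} + \eta_w$ with innovation
SD 0.2 and hard bounds $[-8, 4]$. Misuse items follow a proportional-odds
distribution tied to $L$ (cutpoints $-2.3$, $-0.4$; slope 0.5). A
delivered session lowers the next week's propensity by its arm effect
(default $-0.5$ log-odds for all three arms).

Two points about these choices:

* **Calibration.** The propensity and item parameters were fixed once so
  that the simulated marginals track the published ones: daily completion
  within 3 points of 51.03%, roughly four in five scored weeks at the
  best score of 1 (published: 80.89%), and an early mean risk for the ≥6
  stratum near the published predicted week-1 value. The test suite
  checks these as seeded tolerance bands, not point targets.
* **Arm effects are calibration targets, not facts.** No true effect
  magnitudes are published. The default ($-0.5$ per delivered session,
  equal across arms) was chosen so that the only difference among arms —
  the counselor's 58.6% completion under intention-to-treat crediting,
  a realized handicap of $0.414 \times 0.5 \approx 0.21$ log-odds per
  assignment — is large enough for LinUCB to resolve within one trial's
  ≈2700 decisions. With equal per-delivery effects, any learned
  preference against the counselor arm is attributable to that completion
  gap alone, which is the adaptation property the closed-loop test
  asserts (counselor share over decisions 1–500 exceeding that over
  1900–2400).

What the simulator does **not** emulate: counseling content and
content-mediated heterogeneity, dropout other than call non-completion,
patient-requested reductions in call frequency (folded into the overall
completion rates), the comparison arm of the parent trial, and
reporting biases (under-reporting of misuse). Passing tests therefore
show that the engine's mechanics — scoring, allocation, learning,
logging, analysis — behave correctly under a plausible generative model,
not that the published effect sizes would be reproduced on real patients.

## Evaluation analyses

`fit_decision_mix()` fits a maximum-likelihood multinomial logit of the
chosen session type (reference: brief IVR) on enrollment week (1–130,
linear) and session number (1–12, linear), mirroring the published model
layout. Weekly decisions within a patient are correlated, so standard
errors are patient-clustered sandwich estimates: the bread is the inverse
observed information; the meat sums the analytic scores
$(1[y_i = k] - p_{ik})\,x_i$ within patients with a $G/(G-1)$ correction.
(The installed sandwich-estimator package has no score extractor for
`nnet::multinom`, so the clustered covariance is computed in-package; an
optimizer-based oracle cross-checks the likelihood in the tests.)
`predict_decision_mix()` turns the fit into per-week session-type
probabilities.

`fit_risk_trend()` models weekly scores with a log link and Poisson
variance function. The outcome is a weekly item average — non-integer
with a hard floor at 1 and strong right skew — so quasi-likelihood is
used rather than a Poisson likelihood. Patients enter as random
intercepts (no random slopes), fitted by penalized quasi-likelihood
(`MASS::glmmPQL`); the fixed-effects-only reduction uses
`stats::glm(quasipoisson)` and is cross-checked against a from-scratch
IRLS oracle in the tests. The `"stratified"` spec adds COMM-stratum main
effects (2–5 and ≥6 vs 1) and stratum-by-week interactions. Fitting is
complete-case over scored patient-weeks. The stored `quasi_loglik`
evaluates the Poisson quasi-log-likelihood at the *population-level*
fitted means: conditional fits are unsuitable for comparing nested
fixed-effect structures because random intercepts absorb between-patient
effects. `predict_risk_trajectories()` evaluates
$\exp(\hat\eta)$ over enrollment weeks with session fixed at its sample
mean, one curve per stratum.

The published regression tables for the real cohort are **not** recovery
targets: the underlying patient data is not deposited, and one printed
confidence interval there is internally inconsistent (it does not bracket
its own coefficient). Instead, the tests run parameter-recovery studies
on data simulated from known coefficients — a counselor-vs-brief week
slope of $-0.005$ at ≈2400 decisions, and a (≥6)×week interaction of
$-0.0041$ at 500 patients — requiring ≥90% CI coverage over 200 seeded
replicates each.

## Numerical and size choices

* Ridge floor $\lambda = 1$ keeps every $A_a$ positive definite (minimum
  eigenvalue ≥ 1); solves use `solve()` on the symmetric system directly
  at $d = 7$.
* Tie tolerance: relative $10^{-9}$, scaled by the largest |UCB|.
* Engine loops are $O(\text{decisions})$ with small dense linear algebra;
  a full 228-patient, 141-week trial runs in a few seconds.
* Test problem sizes: full-size trials (2736 decisions) for closed-loop
  and determinism properties; 200-replicate recovery studies at the sizes
  above; 10,000 draws for the tie-conservation property; the whole suite
  completes in a few minutes on one CPU.
* Degenerate inputs fail loudly: single-arm decision logs, fewer than two
  patients with two scored weeks, item codings outside 1–3, non-finite
  rewards, and dimension mismatches all raise diagnostic errors.

## Known limitations

PQL estimation of the random-intercept quasi-Poisson model is approximate
and can be biased for small cluster sizes or large variance components;
the recovery tests bound this in the regimes exercised. The multinomial
cluster sandwich assumes many clusters (228 here). The engine's weekly
batching is one reasonable reading of an unpublished update schedule;
`alpha`, the tie tolerance, and the feature map are all config-exposed
precisely because the deployed values are unknown. The simulator's
single-index propensity cannot represent arm-by-context interactions
(e.g. counseling helping high-COMM patients disproportionately), so the
bandit's *personalization* — as opposed to its arm ranking — is only
weakly exercised by the default environment.
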